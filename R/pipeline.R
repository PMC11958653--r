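#' Questionnaire scores of a study
#'
#' Scores every participant x session: overall NASA-TLX cognitive load (raw
#' mode by default) for the task sessions and the three short-DSSQ states
#' for all sessions.
#'
#' @param study a study from [simulateStudy()] or [readStudy()].
#' @param tlxMode `"raw"` or `"weighted"` (see [scoreTLX()]).
#' @return Data frame: `participant`, `session` (`baseline`/`visual`/
#'   `code`), `cl` (`NA` at baseline), `engagement`, `distress`, `worry`.
#' @export
questionnaireScores <- function(study, tlxMode = "raw") {
  rows <- list()
  for (p in names(study$participants)) {
    for (sess in study$participants[[p]]$sessions) {
      cl <- if (!is.null(sess$tlxRatings))
        scoreTLX(sess$tlxRatings, mode = tlxMode)$cl else NA_real_
      ds <- scoreDSSQ(sess$dssqItems)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, session = sess$condition, cl = cl,
        engagement = ds[["engagement"]], distress = ds[["distress"]],
        worry = ds[["worry"]])
    }
  }
  do.call(rbind, rows)
}

#' Performance metrics of a study
#'
#' Number of task repetitions (NTR), task completion time (TCT, minutes) and
#' session-averaged assembly-precision SD for every participant x
#' instruction session. Per-trial precision compares the placed marker
#' centers with the trial's reference pattern via [precisionSD()].
#'
#' @param study a study from [simulateStudy()] or [readStudy()].
#' @return Data frame: `participant`, `session`, `ntr`, `tctMin`,
#'   `precisionSd`.
#' @export
performanceMetrics <- function(study) {
  pats <- study$config$patterns
  rows <- list()
  for (p in names(study$participants)) {
    for (sess in study$participants[[p]]$sessions) {
      if (is.null(sess$trials)) next
      sds <- vapply(split(sess$trials, sess$trials$trial), function(tr) {
        precisionSD(tr, pats[[tr$pattern[1]]])$sd
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, session = sess$condition, ntr = sess$ntr,
        tctMin = sess$tct / 60, precisionSd = sessionPrecision(sds))
    }
  }
  do.call(rbind, rows)
}

pairedByParticipant <- function(df, col, a = "visual", b = "code") {
  wide <- merge(df[df$session == a, c("participant", col)],
                df[df$session == b, c("participant", col)],
                by = "participant", suffixes = c(".a", ".b"))
  list(x = wide[[paste0(col, ".a")]], y = wide[[paste0(col, ".b")]])
}

#' Subjective and performance statistics battery
#'
#' Reproduces the study's statistical layout on any study object: gated
#' paired comparisons (visual vs code) for cognitive load, NTR, TCT and
#' precision, and sphericity-corrected repeated-measures ANOVAs with post
#' hoc tests for the three DSSQ states across baseline / post-visual /
#' post-code.
#'
#' @param scores output of [questionnaireScores()].
#' @param perf output of [performanceMetrics()] (optional; `NULL` skips the
#'   performance rows).
#' @param posthocAdjust p-adjustment for the ANOVA post hoc tests.
#' @return List with `paired` (data frame: measure, shapiroP, test, Z,
#'   effectSize, pValue) and `anova` (named list of [rmAnova()] results for
#'   engagement, distress, worry).
#' @export
statsBattery <- function(scores, perf = NULL, posthocAdjust = "holm") {
  pairedRow <- function(measure, x, y) {
    pc <- pairedCompare(x, y)
    data.frame(measure = measure, shapiroP = pc$shapiroP, test = pc$test,
               Z = pc$Z, effectSize = pc$effectSize, pValue = pc$pValue)
  }
  rows <- list()
  cl <- pairedByParticipant(scores, "cl")
  rows$cl <- pairedRow("cognitive load (visual vs code)", cl$x, cl$y)
  if (!is.null(perf)) {
    for (m in c("ntr", "tctMin", "precisionSd")) {
      pp <- pairedByParticipant(perf, m)
      rows[[m]] <- pairedRow(paste0(m, " (visual vs code)"), pp$x, pp$y)
    }
  }
  anova <- list()
  for (state in c("engagement", "distress", "worry")) {
    wide <- stats::reshape(
      scores[, c("participant", "session", state)],
      idvar = "participant", timevar = "session", direction = "wide")
    m <- as.matrix(wide[, paste(state, c("baseline", "visual", "code"),
                                sep = ".")])
    colnames(m) <- c("pre", "postVisual", "postCode")
    anova[[state]] <- rmAnova(m[stats::complete.cases(m), , drop = FALSE],
                              posthocAdjust = posthocAdjust)
  }
  list(paired = do.call(rbind, rows), anova = anova)
}

#' Condition classification battery
#'
#' Fits the four condition classifiers on a segment feature table: the
#' multinomial model (baseline as reference) over all three sessions and the
#' three binary models (visual vs baseline, code vs baseline, code vs
#' visual), each with backward elimination from the full candidate set, and
#' evaluates them in-sample (optionally also by stratified k-fold).
#'
#' @param ff feature data frame from [featureFrame()].
#' @param candidates candidate feature names (default: every numeric feature
#'   column).
#' @param removalAlpha backward-elimination threshold.
#' @param kFold also run stratified k-fold evaluation (default FALSE).
#' @return Named list (`multinomial`, `visual_vs_baseline`,
#'   `code_vs_baseline`, `code_vs_visual`) of lists with `selection`,
#'   `fit`, `metrics` (and `metricsKFold` when requested).
#' @export
classificationBattery <- function(ff, candidates = NULL, removalAlpha = 0.10,
                                  kFold = FALSE) {
  if (is.null(candidates))
    candidates <- setdiff(names(ff)[vapply(ff, is.numeric, logical(1))],
                          c("windowIndex"))
  runOne <- function(data, ref, name) {
    sel <- backwardEliminate(data, candidates, "session",
                             referenceClass = ref,
                             removalAlpha = removalAlpha)
    mt <- evaluateModel(sel$fit, data)
    out <- list(selection = sel, fit = sel$fit, metrics = mt)
    if (kFold)
      out$metricsKFold <- evaluateModel(sel$fit, data, scheme = "k-fold",
                                        candidates = candidates,
                                        removalAlpha = removalAlpha)
    out
  }
  sub <- function(a, b) ff[ff$session %in% c(a, b), , drop = FALSE]
  list(
    multinomial = runOne(ff, "baseline", "multinomial"),
    visual_vs_baseline = runOne(sub("visual", "baseline"), "baseline",
                                "visual_vs_baseline"),
    code_vs_baseline = runOne(sub("code", "baseline"), "baseline",
                              "code_vs_baseline"),
    code_vs_visual = runOne(sub("code", "visual"), "visual",
                            "code_vs_visual"))
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: generate (or load) a study, score
#' questionnaires and assembly performance, run the statistical battery
#' and -- when the study carries signals -- extract the segment feature
#' table and run the classification battery. With an output directory the
#' tables and a manifest (seed, configuration fingerprint) are written as
#' delimited/JSON files. Identical configuration and seed give identical
#' reports.
#'
#' @param config a [studyConfig()], or a directory path for [readStudy()].
#' @param outputDir optional output directory (created if needed).
#' @param includeAccel include accelerometer features in the feature table.
#' @param runPhysio run the physiological feature/classification stages
#'   (default: the study's `includeSignals` flag).
#' @param kFold also report stratified k-fold classification metrics.
#' @return A report list: `study`, `scores`, `performance`, `stats`,
#'   and (when physiological stages ran) `features`, `classification`.
#' @export
runPipeline <- function(config, outputDir = NULL, includeAccel = FALSE,
                        runPhysio = NULL, kFold = FALSE) {
  study <- if (is.character(config)) readStudy(config)
           else simulateStudy(config)
  if (is.null(runPhysio)) runPhysio <- isTRUE(study$config$includeSignals)
  scores <- questionnaireScores(study)
  perf <- performanceMetrics(study)
  report <- list(study = study, scores = scores, performance = perf,
                 stats = statsBattery(scores, perf))
  if (runPhysio) {
    ft <- buildFeatureTable(study, includeAccel = includeAccel)
    ff <- featureFrame(ft)
    report$features <- ft
    report$classification <- classificationBattery(ff, kFold = kFold)
  }
  if (!is.null(outputDir)) writeReport(report, outputDir)
  invisible(report)
}

#' Write the pipeline report to disk
#'
#' Serializes the score, performance and statistics tables as CSV, the
#' classification summary as JSON, and a manifest holding the seed and a
#' configuration fingerprint.
#'
#' @param report a report from [runPipeline()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$scores, file.path(dir, "questionnaire_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$stats$paired, file.path(dir, "paired_tests.csv"),
                   row.names = FALSE)
  anovaTab <- do.call(rbind, lapply(names(report$stats$anova), function(s) {
    a <- report$stats$anova[[s]]
    data.frame(state = s, mauchlyP = a$mauchly$pValue,
               correction = a$correction, epsilonHF = a$epsilonHF,
               anovaP = a$correctedP)
  }))
  utils::write.csv(anovaTab, file.path(dir, "rm_anova.csv"),
                   row.names = FALSE)
  if (!is.null(report$classification)) {
    cls <- lapply(report$classification, function(m) {
      list(selected = m$fit$selectedFeatures,
           B = as.data.frame(m$fit$B),
           pValues = as.list(m$fit$pValues),
           chiSquare = m$fit$chiSquare, df = m$fit$df,
           modelP = m$fit$modelP,
           metrics = m$metrics[c("accuracy", "precision", "recall")])
    })
    jsonlite::write_json(cls, file.path(dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  cfg <- report$study$config
  manifest <- list(
    seed = cfg$seed,
    nParticipants = cfg$nParticipants,
    fs = cfg$fs,
    configHash = sum(utf8ToInt(paste(utils::capture.output(
      utils::str(cfg[setdiff(names(cfg), "patterns")])), collapse = ""))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a synthetic study to a directory layout
#'
#' One delimited file per signal (`time_s,value` or `time_s,x,y,z`), a
#' questionnaire item table, a trials table and a JSON manifest with labels,
#' durations and session metadata.
#'
#' @param study a study from [simulateStudy()].
#' @param dir target directory.
#' @return The directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  qRows <- list(); tRows <- list(); meta <- list()
  for (p in names(study$participants)) {
    part <- study$participants[[p]]
    for (sn in names(part$sessions)) {
      sess <- part$sessions[[sn]]
      meta[[paste(p, sn, sep = "_")]] <- list(
        participant = p, sessionName = sn, condition = sess$condition,
        durationS = sess$durationS,
        ntr = if (is.null(sess$ntr)) NA else sess$ntr,
        tct = if (is.null(sess$tct)) NA else sess$tct,
        subgroup = part$subgroup)
      for (s in c("engagement", "distress", "worry")) {
        v <- sess$dssqItems[[s]]
        qRows[[length(qRows) + 1L]] <- data.frame(
          participant = p, sessionName = sn, instrument = paste0("dssq_", s),
          item = seq_along(v), value = v)
      }
      if (!is.null(sess$tlxRatings))
        qRows[[length(qRows) + 1L]] <- data.frame(
          participant = p, sessionName = sn, instrument = "tlx",
          item = names(sess$tlxRatings), value = unname(sess$tlxRatings))
      if (!is.null(sess$trials)) {
        tr <- sess$trials
        tr$participant <- p; tr$sessionName <- sn
        tRows[[length(tRows) + 1L]] <- tr
      }
      if (!is.null(sess$ppg)) {
        fs <- samplingRate(sess$ppg)
        for (ch in c("ppg", "gsr")) {
          v <- samples(sess[[ch]])
          utils::write.csv(
            data.frame(time_s = (seq_along(v) - 1) / fs, value = v),
            file.path(dir, "signals", paste(p, sn, ch, "csv", sep = ".")),
            row.names = FALSE)
        }
        acc <- sess$accel
        utils::write.csv(
          data.frame(time_s = (seq_along(acc@x) - 1) / acc@fs,
                     x = acc@x, y = acc@y, z = acc@z),
          file.path(dir, "signals", paste(p, sn, "accel.csv", sep = ".")),
          row.names = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, qRows),
                   file.path(dir, "questionnaires.csv"), row.names = FALSE)
  if (length(tRows))
    utils::write.csv(do.call(rbind, tRows), file.path(dir, "trials.csv"),
                     row.names = FALSE)
  pats <- lapply(study$config$patterns, function(p) p)
  jsonlite::write_json(
    list(fs = study$config$fs, seed = study$config$seed,
         sessionLengthS = study$config$sessionLengthS,
         baselineLengthS = study$config$baselineLengthS,
         minRepetitions = study$config$minRepetitions,
         patterns = pats, sessions = unname(meta)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study from a directory layout
#'
#' Inverse of [writeStudy()]: reconstructs the study container (signals,
#' questionnaire items, trials, session metadata) from the delimited files
#' and manifest. Columns are addressed by name, so header order is free.
#'
#' @param dir directory written by [writeStudy()].
#' @return A study list usable by the scoring, feature and statistics
#'   stages.
#' @export
readStudy <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no participants found: missing ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!length(manifest$sessions)) stop("no participants found in ", dir)
  q <- utils::read.csv(file.path(dir, "questionnaires.csv"))
  trials <- if (file.exists(file.path(dir, "trials.csv")))
    utils::read.csv(file.path(dir, "trials.csv")) else NULL
  sessions <- manifest$sessions
  participants <- list()
  for (r in seq_len(nrow(sessions))) {
    m <- sessions[r, ]
    p <- m$participant; sn <- m$sessionName
    sess <- list(condition = m$condition,
                 durationS = as.numeric(m$durationS))
    if (!is.null(m$ntr) && !is.na(m$ntr)) sess$ntr <- as.numeric(m$ntr)
    if (!is.null(m$tct) && !is.na(m$tct)) sess$tct <- as.numeric(m$tct)
    qi <- q[q$participant == p & q$sessionName == sn, ]
    sess$dssqItems <- lapply(
      stats::setNames(nm = c("engagement", "distress", "worry")),
      function(s) qi$value[qi$instrument == paste0("dssq_", s)][
        order(as.integer(qi$item[qi$instrument == paste0("dssq_", s)]))])
    tlx <- qi[qi$instrument == "tlx", ]
    if (nrow(tlx)) sess$tlxRatings <- stats::setNames(tlx$value, tlx$item)
    if (!is.null(trials)) {
      tr <- trials[trials$participant == p & trials$sessionName == sn, ]
      if (nrow(tr)) sess$trials <- tr
    }
    sigFile <- function(ch)
      file.path(dir, "signals", paste(p, sn, ch, "csv", sep = "."))
    if (file.exists(sigFile("ppg"))) {
      pg <- utils::read.csv(sigFile("ppg"))
      fs <- 1 / stats::median(diff(pg$time_s))
      sess$ppg <- RawSignal(pg$value, fs, channel = "ppg")
      gs <- utils::read.csv(sigFile("gsr"))
      sess$gsr <- RawSignal(gs$value, fs, channel = "gsr")
      ac <- utils::read.csv(sigFile("accel"))
      sess$accel <- TriaxialSignal(ac$x, ac$y, ac$z, fs)
    }
    if (is.null(participants[[p]]))
      participants[[p]] <- list(subgroup = m$subgroup, sessions = list())
    participants[[p]]$sessions[[sn]] <- sess
  }
  cfg <- studyConfig(
    nParticipants = max(2L, length(participants)),
    fs = manifest$fs, sessionLengthS = manifest$sessionLengthS,
    baselineLengthS = manifest$baselineLengthS,
    minRepetitions = manifest$minRepetitions,
    patterns = lapply(manifest$patterns, as.data.frame),
    seed = manifest$seed)
  list(config = cfg, scheme = cfg$groupScheme, participants = participants)
}
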