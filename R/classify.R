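# Balanced group folds: whole sessions are assigned to folds, same-class
# sessions are spread over different folds, and every training fold must
# contain all classes.
group_folds <- function(groups, y, k, seed) {
  sessions <- unique(groups)
  cls <- vapply(sessions, function(s) {
    lab <- unique(as.character(y[groups == s]))
    if (length(lab) != 1) stop("session ", s, " carries mixed labels")
    lab
  }, "")
  if (k > length(sessions))
    stop("k = ", k, " exceeds the number of sessions (", length(sessions), ")")
  tab <- table(cls)
  if (any(tab < 2))
    stop("every class needs at least 2 sessions for group-aware folding")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of <- stats::setNames(integer(length(sessions)), sessions)
  offset <- 0L
  for (cl in sample(names(tab))) {
    s_cl <- sample(sessions[cls == cl])
    fold_of[as.character(s_cl)] <- ((offset + seq_along(s_cl) - 1L) %% k) + 1L
    offset <- offset + length(s_cl)
  }
  for (f in seq_len(k)) {
    train_cls <- unique(cls[fold_of != f])
    if (length(train_cls) < length(tab))
      stop("fold ", f, " leaves a class absent from training; ",
           "need more sessions per class")
  }
  fold_of
}

#' Cross-validated linear-SVM accuracy
#'
#' Four-class linear-kernel SVM evaluated by stratified, session-grouped
#' k-fold cross-validation: windows of one session never span the
#' train/test split, same-class sessions are spread over folds, and features
#' are standardized with training-fold statistics only.
#'
#' @param ds A `feature_dataset` from [assemble_dataset()].
#' @param k Number of folds (default 4).
#' @param seed Seed for the fold assignment.
#' @param cost SVM regularization constant C (default 1, untuned).
#' @return Mean test accuracy over folds, in percent.
#' @export
crossval_svm <- function(ds, k = 4, seed = 1L, cost = 1) {
  stopifnot(inherits(ds, "feature_dataset"))
  y <- droplevels(ds$y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  fold_of <- group_folds(ds$groups, y, k, seed)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    test <- ds$groups %in% names(fold_of)[fold_of == f]
    Xtr <- ds$X[!test, , drop = FALSE]
    Xte <- ds$X[test, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
    fit <- e1071::svm(Xtr, droplevels(y[!test]), kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- stats::predict(fit, Xte)
    accs[f] <- mean(as.character(pred) == as.character(y[test]))
  }
  100 * mean(accs)
}

#' Per-subject accuracy grid over features, bands and conditions
#'
#' Computes every feature kind once per segment (PSD from the broadband
#' spectrum; DE from the band decomposition; DASM/DCAU as pair differences of
#' DE) and evaluates [crossval_svm()] for each cell of the
#' feature x band x pattern x condition grid of one subject.
#'
#' @param segments Either a list of `session_segment`s of one subject (as
#'   from [preprocess_recording()]; bands are then filtered per segment), or
#'   a preprocessed `eeg_recording` (as from [preprocess_chain()]; the
#'   recording is band-filtered once per band, which is much faster).
#' @param kinds Feature kinds to evaluate.
#' @param band_rows Band rows of the grid; defaults to the five bands plus
#'   `"total"` (all-band concatenation).
#' @param k,seed,cost Passed to [crossval_svm()].
#' @param bands Band definition table.
#' @return data.frame of class `accuracy_table` with columns `subject`,
#'   `pattern`, `condition`, `feature`, `band`, `accuracy` (percent). Cells
#'   whose CV preconditions fail are recorded as `NA`, not imputed.
#' @export
subject_accuracy_grid <- function(segments,
                                  kinds = c("PSD", "DE", "DASM", "DCAU"),
                                  band_rows = c(eeg_bands()$name, "total"),
                                  k = 4, seed = 1L, cost = 1,
                                  bands = eeg_bands()) {
  band_lists <- NULL
  if (inherits(segments, "eeg_recording")) {
    rec <- segments
    segments <- segment_sessions(rec)
    if (any(c("DE", "DASM", "DCAU") %in% kinds)) {
      band_segs <- lapply(band_decompose_recording(rec, bands),
                          segment_sessions)
      band_lists <- lapply(seq_along(segments), function(i)
        lapply(seq_len(nrow(bands)), function(b) {
          s <- band_segs[[b]][[i]]
          s$band <- bands$name[b]
          s
        }))
    }
  }
  stopifnot(length(segments) >= 1)
  subject <- segments[[1]]$subject
  # channel-wise tensors (PSD/DE) are restricted to the 63 data channels;
  # the reconstructed reference only serves the pair tables
  data_chans <- intersect(segments[[1]]$channel_names,
                          montage_channels(standard_montage()))
  if (!length(data_chans)) data_chans <- segments[[1]]$channel_names
  feats <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    out <- list()
    if ("PSD" %in% kinds)
      out$PSD <- tensor_select_units(psd_features(seg, bands), data_chans)
    if (any(c("DE", "DASM", "DCAU") %in% kinds)) {
      de <- de_features(if (is.null(band_lists)) seg else band_lists[[i]],
                        bands)
      if ("DE" %in% kinds) out$DE <- tensor_select_units(de, data_chans)
      if ("DASM" %in% kinds) out$DASM <- dasm_features(de)
      if ("DCAU" %in% kinds) out$DCAU <- dcau_features(de)
    }
    out
  })
  meta <- data.frame(
    session = vapply(segments, function(s) s$session, 0L),
    emotion = vapply(segments, function(s) s$emotion, ""),
    pattern = vapply(segments, function(s) s$pattern, ""),
    condition = vapply(segments, function(s) s$condition, ""))
  res <- list()
  for (pat in sort(unique(meta$pattern)))
    for (cond in c("non-haptic", "haptic"))
      for (kind in kinds)
        for (band in band_rows) {
          sel <- which(meta$pattern == pat & meta$condition == cond)
          acc <- tryCatch({
            ds <- assemble_dataset(lapply(feats[sel], `[[`, kind),
                                   meta$emotion[sel], meta$session[sel],
                                   band = band)
            crossval_svm(ds, k = k, seed = seed, cost = cost)
          }, error = function(e) NA_real_)
          res[[length(res) + 1L]] <- data.frame(
            subject = subject, pattern = pat, condition = cond,
            feature = kind, band = band, accuracy = acc)
        }
  out <- do.call(rbind, res)
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' Evaluate the accuracy grid for a whole experiment
#'
#' Preprocesses each subject's recording and computes its accuracy grid;
#' returns the stacked per-subject table plus across-subject means.
#'
#' @param recordings List of `eeg_recording`s (one per subject).
#' @param ... Passed to [subject_accuracy_grid()].
#' @param fs_target,ica Passed to [preprocess_recording()].
#' @return List with `table` (per-subject `accuracy_table`) and `means`
#'   (across-subject mean accuracy per grid cell).
#' @export
evaluate_experiment <- function(recordings, fs_target = 200, ica = FALSE,
                                ...) {
  tabs <- lapply(recordings, function(rec) {
    pre <- preprocess_chain(rec, fs_target = fs_target, ica = ica)
    subject_accuracy_grid(pre, ...)
  })
  table <- do.call(rbind, tabs)
  class(table) <- c("accuracy_table", "data.frame")
  means <- stats::aggregate(accuracy ~ pattern + condition + feature + band,
                            data = table, FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
  list(table = table, means = means)
}
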