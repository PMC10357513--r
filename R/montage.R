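#' Standard 64-channel 10-20 montage
#'
#' Returns the fixed electrode layout used throughout the pipeline: a
#' 64-channel active-electrode cap laid out on the international 10-20/10-10
#' system, recorded against an FCz reference with Fpz as ground, so that 63
#' data channels are available. Scalp coordinates are a standard
#' azimuthal-equidistant (polar) projection onto the unit disc, head radius 1
#' at the outer 10% ring (below-ring electrodes such as FT9/FT10, TP9/TP10 and
#' CB1/CB2 project slightly outside it).
#'
#' @return An object of class `eeg_montage`: a list with
#'   \describe{
#'     \item{channels}{data.frame with columns `label`, `role`
#'       (`"data"`, `"reference"`, `"ground"`), `x`, `y`.}
#'     \item{reference}{reference label, `"FCz"`.}
#'     \item{ground}{ground label, `"Fpz"`.}
#'   }
#' @examples
#' m <- standard_montage()
#' length(montage_channels(m))  # 63 usable channels
#' @export
standard_montage <- function() {
  path <- system.file("extdata", "montage_standard64.csv", package = "hapticEEG",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(tab$label))
  m <- structure(
    list(channels = tab,
         reference = tab$label[tab$role == "reference"],
         ground = tab$label[tab$role == "ground"]),
    class = "eeg_montage")
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  usable <- montage_channels(m)
  if (length(usable) != 63L)
    stop("montage must expose exactly 63 usable channels, got ", length(usable))
  for (p in list(dasm_pairs(m), dcau_pairs(m))) {
    miss <- setdiff(toupper(c(p$a, p$b)), toupper(m$channels$label))
    if (length(miss))
      stop("pair table references unknown channels: ", paste(miss, collapse = ", "))
  }
  invisible(m)
}

#' Usable (data) channel labels of a montage
#'
#' Excludes the reference (FCz) and ground (Fpz) electrodes.
#' @param m An `eeg_montage`.
#' @return Character vector of 63 labels, in montage order.
#' @export
montage_channels <- function(m) {
  stopifnot(inherits(m, "eeg_montage"))
  m$channels$label[m$channels$role == "data"]
}

#' 2-D scalp positions for given labels
#'
#' @param m An `eeg_montage`.
#' @param labels Channel labels (matched case-insensitively); defaults to all
#'   usable channels.
#' @return data.frame with columns `label`, `x`, `y` in the requested order.
#' @export
montage_positions <- function(m, labels = montage_channels(m)) {
  stopifnot(inherits(m, "eeg_montage"))
  idx <- match(toupper(labels), toupper(m$channels$label))
  if (anyNA(idx))
    stop("unknown channel label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  data.frame(label = m$channels$label[idx],
             x = m$channels$x[idx], y = m$channels$y[idx])
}

read_pair_table <- function(file, m, kind) {
  path <- system.file("extdata", file, package = "hapticEEG", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- c("a", "b")
  bad <- setdiff(toupper(c(tab$a, tab$b)), toupper(m$channels$label))
  if (length(bad))
    stop("pair table '", kind, "' references channels absent from the montage: ",
         paste(bad, collapse = ", "))
  tab$kind <- kind
  tab
}

#' Hemispheric-asymmetry (DASM) electrode pairs
#'
#' The 28 left-right homologous electrode pairs over which hemispheric
#' asymmetry differences of differential entropy are computed. The left
#' electrode is in column `a`, its right homolog in column `b`, in the
#' conventional printed order starting with (Fp1, Fp2).
#'
#' @param m An `eeg_montage`, default [standard_montage()].
#' @return data.frame with columns `a`, `b`, `kind = "hemispheric"` (28 rows).
#' @export
dasm_pairs <- function(m = standard_montage()) {
  read_pair_table("pairs_dasm.csv", m, "hemispheric")
}

#' Frontal-posterior (DCAU) electrode pairs
#'
#' The 22 frontal-posterior electrode pairs over which caudality differences
#' of differential entropy are computed. The frontal electrode is in column
#' `a`, its posterior partner in column `b`. The table includes FCz-CPz (FCz
#' is the online reference and is reconstructed after common-average
#' re-referencing) and AF3-CB1 / AF4-CB2.
#'
#' @inheritParams dasm_pairs
#' @return data.frame with columns `a`, `b`, `kind = "frontal-posterior"`
#'   (22 rows).
#' @export
dcau_pairs <- function(m = standard_montage()) {
  read_pair_table("pairs_dcau.csv", m, "frontal-posterior")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", sum(x$channels$role == "data"), " data channels, ",
      "reference ", x$reference, ", ground ", x$ground, "\n", sep = "")
  invisible(x)
}
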