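# One-off generator for inst/extdata montage + pair-table resources.
ring <- function(labels, phis) data.frame(label = labels, r = 1, phi = phis)
interp_row <- function(mid_r, mid_phi, out_r, out_phi, labels_left, labels_right, fracs) {
  # interpolate along the arc between the midline point and the circumference point
  rs <- mid_r + fracs * (out_r - mid_r)
  ph <- mid_phi + fracs * (out_phi - mid_phi)
  rbind(data.frame(label = labels_left, r = rs, phi = -ph),
        data.frame(label = labels_right, r = rs, phi = ph))
}
tab <- rbind(
  ring(c("Fp1", "Fp2"), c(-18, 18)),
  ring(c("AF7", "AF8"), c(-36, 36)),
  interp_row(0.75, 0, 1, 36, "AF3", "AF4", 0.5),
  ring(c("F7", "F8"), c(-54, 54)),
  data.frame(label = "Fz", r = 0.5, phi = 0),
  interp_row(0.5, 0, 1, 54, c("F1", "F3", "F5"), c("F2", "F4", "F6"), c(0.25, 0.5, 0.75)),
  ring(c("FT7", "FT8"), c(-72, 72)),
  data.frame(label = c("FT9", "FT10"), r = 1.15, phi = c(-72, 72)),
  data.frame(label = "FCz", r = 0.25, phi = 0),
  interp_row(0.25, 0, 1, 72, c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6"), c(0.25, 0.5, 0.75)),
  ring(c("T7", "T8"), c(-90, 90)),
  data.frame(label = c("Cz", "C1", "C3", "C5", "C2", "C4", "C6"),
             r = c(0, 0.25, 0.5, 0.75, 0.25, 0.5, 0.75),
             phi = c(0, -90, -90, -90, 90, 90, 90)),
  ring(c("TP7", "TP8"), c(-108, 108)),
  data.frame(label = c("TP9", "TP10"), r = 1.15, phi = c(-108, 108)),
  data.frame(label = "CPz", r = 0.25, phi = 180),
  interp_row(0.25, 180, 1, 108, c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6"), c(0.25, 0.5, 0.75)),
  ring(c("P7", "P8"), c(-126, 126)),
  data.frame(label = "Pz", r = 0.5, phi = 180),
  interp_row(0.5, 180, 1, 126, c("P1", "P3", "P5"), c("P2", "P4", "P6"), c(0.25, 0.5, 0.75)),
  ring(c("PO7", "PO8"), c(-144, 144)),
  interp_row(0.75, 180, 1, 144, "PO3", "PO4", 0.5),
  ring(c("O1", "O2"), c(-162, 162)),
  data.frame(label = "Oz", r = 1, phi = 180),
  data.frame(label = c("CB1", "CB2"), r = 1.15, phi = c(-150, 150)),
  data.frame(label = "Fpz", r = 1, phi = 0)
)
tab$x <- round(tab$r * sin(tab$phi * pi / 180), 6)
tab$y <- round(tab$r * cos(tab$phi * pi / 180), 6)
tab$role <- ifelse(tab$label == "FCz", "reference",
            ifelse(tab$label == "Fpz", "ground", "data"))
order_labels <- c(
  "Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "PO4", "PO8", "O1", "Oz", "O2", "CB1", "CB2",
  "FCz", "Fpz")
stopifnot(setdiff(order_labels, tab$label) == character(0),
          setdiff(tab$label, order_labels) == character(0),
          !anyDuplicated(tab$label))
tab <- tab[match(order_labels, tab$label), c("label", "role", "x", "y")]
stopifnot(sum(tab$role == "data") == 63)
write.csv(tab, "inst/extdata/montage_standard64.csv", row.names = FALSE, quote = FALSE)

dasm <- c("Fp1-Fp2", "F7-F8", "F3-F4", "FT7-FT8", "FC3-FC4", "T7-T8", "P7-P8",
          "C3-C4", "TP7-TP8", "CP3-CP4", "P3-P4", "O1-O2", "AF3-AF4", "F5-F6",
          "FC5-FC6", "FC1-FC2", "C5-C6", "C1-C2", "CP5-CP6", "CP1-CP2",
          "AF7-AF8", "P5-P6", "P1-P2", "PO7-PO8", "PO3-PO4", "FT9-FT10",
          "TP9-TP10", "F1-F2")
dcau <- c("FT7-TP7", "FC5-CP5", "FC3-CP3", "FC1-CP1", "FCz-CPz", "FC2-CP2",
          "FC4-CP4", "FC6-CP6", "FT8-TP8", "F7-P7", "F5-P5", "F3-P3", "F1-P1",
          "Fz-Pz", "F2-P2", "F4-P4", "F6-P6", "F8-P8", "Fp1-O1", "Fp2-O2",
          "AF3-CB1", "AF4-CB2")
stopifnot(length(dasm) == 28, length(dcau) == 22)
split2 <- function(x) do.call(rbind, strsplit(x, "-", fixed = TRUE))
d1 <- split2(dasm); d2 <- split2(dcau)
write.csv(data.frame(left = d1[, 1], right = d1[, 2]),
          "inst/extdata/pairs_dasm.csv", row.names = FALSE, quote = FALSE)
write.csv(data.frame(frontal = d2[, 1], posterior = d2[, 2]),
          "inst/extdata/pairs_dcau.csv", row.names = FALSE, quote = FALSE)
cat("written\n")
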