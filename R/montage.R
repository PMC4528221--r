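## Idealized spherical 10/20 montage. No digitized electrode positions are
## available, so positions are constructed on a unit sphere from the 10/20
## system's defining arcs: Cz at the vertex (0,0,1), +y toward the nasion,
## +x toward the right preauricular point. Principal sites lie on the
## midline, the coronal ear-to-ear arc, and the 10%-circumference circle;
## intermediate 10%-system sites (F3/F4, FC.., CP.., P3/P4, PO..) are
## normalized great-circle midpoints of their flanking principal sites.

deg2rad <- function(d) d * pi / 180

## position from inclination (degrees from vertex) and azimuth (degrees
## clockwise from nasion direction +y when seen from above; negative = left)
incl_az <- function(incl, az) {
  ti <- deg2rad(incl); ta <- deg2rad(az)
  c(x = sin(ti) * sin(ta), y = sin(ti) * cos(ta), z = cos(ti))
}

unit <- function(v) v / sqrt(sum(v^2))

build_montage_table <- function() {
  p <- list()
  ## midline (nasion->inion arc, 180 deg over the top)
  p$Fpz <- incl_az(72, 0); p$Fz <- incl_az(36, 0); p$Cz <- c(x = 0, y = 0, z = 1)
  p$Pz <- incl_az(36, 180); p$Oz <- incl_az(72, 180)
  ## coronal arc (left ear -> vertex -> right ear)
  p$T7 <- incl_az(72, -90); p$C3 <- incl_az(36, -90)
  p$C4 <- incl_az(36, 90); p$T8 <- incl_az(72, 90)
  ## 10%-circumference circle (inclination 72), azimuth steps of 36 deg
  p$Fp1 <- incl_az(72, -18); p$Fp2 <- incl_az(72, 18)
  p$F7 <- incl_az(72, -54); p$F8 <- incl_az(72, 54)
  p$P7 <- incl_az(72, -126); p$P8 <- incl_az(72, 126)
  p$O1 <- incl_az(72, -162); p$O2 <- incl_az(72, 162)
  ## intermediate 10/20 sites on the frontal/parietal arcs
  p$F3 <- unit(p$Fz + p$F7); p$F4 <- unit(p$Fz + p$F8)
  p$P3 <- unit(p$Pz + p$P7); p$P4 <- unit(p$Pz + p$P8)
  ## 10%-system rows between the frontal/central and central/parietal rows
  p$FC1 <- unit(p$F3 + p$C3 + p$Fz + p$Cz); p$FC2 <- unit(p$F4 + p$C4 + p$Fz + p$Cz)
  p$FC5 <- unit(p$F7 + p$T7 + p$F3 + p$C3); p$FC6 <- unit(p$F8 + p$T8 + p$F4 + p$C4)
  p$CP1 <- unit(p$C3 + p$P3 + p$Cz + p$Pz); p$CP2 <- unit(p$C4 + p$P4 + p$Cz + p$Pz)
  p$CP5 <- unit(p$T7 + p$P7 + p$C3 + p$P3); p$CP6 <- unit(p$T8 + p$P8 + p$C4 + p$P4)
  ## parieto-occipital inferior row (below the 10% circle)
  p$PO9 <- incl_az(90, -144); p$PO10 <- incl_az(90, 144)
  p$TP9 <- incl_az(90, -108); p$TP10 <- incl_az(90, 108)
  mat <- do.call(rbind, p)
  colnames(mat) <- c("x", "y", "z")
  mat
}

MONTAGE_TABLE <- build_montage_table()

#' Motor-cortex 9-channel subset
#'
#' The clinically practical subset over the sensorimotor cortex.
#' @return Character vector of 9 channel labels.
#' @export
motor_channels <- function() c("C3", "C4", "Cz", "F3", "F4", "P3", "P4", "T7", "T8")

#' Default 30-channel EEG labels
#'
#' A 32-channel cap layout with TP9/TP10 repurposed for the bipolar EMG pair,
#' leaving 30 scalp channels. Includes the full motor subset.
#' @return Character vector of 30 labels.
#' @export
default_eeg_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10")
}

#' Default channel labels including the EMG pair
#' @return Character vector of 32 labels (30 EEG + EMG1, EMG2).
#' @export
default_channel_labels <- function() c(default_eeg_labels(), "EMG1", "EMG2")

#' Standard spherical montage for 10/20-style labels
#'
#' Returns unit-sphere positions for the requested labels, constructed from
#' the 10/20 system's angular conventions (Cz at the vertex; left/right
#' homologs mirror in the sagittal plane).
#'
#' @param labels Channel labels (extended 10/20 nomenclature).
#' @return A `montage`: list with `labels` and `positions` (n x 3 matrix of
#'   unit vectors, rows named by label).
#' @export
standard_montage <- function(labels = default_eeg_labels()) {
  unknown <- setdiff(labels, rownames(MONTAGE_TABLE))
  if (length(unknown)) {
    stop_invalid(sprintf("unknown electrode label(s): %s", paste(unknown, collapse = ", ")))
  }
  pos <- MONTAGE_TABLE[labels, , drop = FALSE]
  structure(list(labels = labels, positions = pos), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes on the unit sphere\n", length(x$labels)))
  invisible(x)
}

#' Angular distance (radians) from every montage electrode to one electrode
#' @keywords internal
montage_angles_to <- function(montage, label) {
  ref <- montage$positions[label, ]
  cosang <- pmin(1, pmax(-1, montage$positions %*% ref))
  acos(drop(cosang))
}
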