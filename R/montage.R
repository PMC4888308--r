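#' Standard 32-channel 10-20 montage
#'
#' Electrode positions for the 32-channel cap used throughout the package,
#' constructed from the geometry that defines the 10-20 system: positions
#' are laid out at 10%/20% steps along great-circle arcs of a unit sphere
#' (vertex at `Cz`), so homologous left/right sites are exact mirror
#' images. The set covers every electrode named in the per-band ANOVA
#' summaries plus the standard complements of a 32-channel cap (including
#' mastoids `M1`/`M2`).
#'
#' @param labels Optional character vector restricting (and ordering) the
#'   returned montage. Unknown labels are an error.
#' @return A data frame with columns `label`, `x`, `y`, `z` (unit-sphere
#'   coordinates: x = right, y = anterior, z = superior) and `px`, `py`
#'   (2-D azimuthal-equidistant projection from the vertex, `Cz` at the
#'   origin, outer 10% ring at radius 0.8).
#' @export
#' @examples
#' m <- montage_1020()
#' nrow(m)            # 32
#' m[m$label == "Cz", c("x", "y", "z")]
montage_1020 <- function(labels = NULL) {
  pos <- montage_positions()
  if (!is.null(labels)) {
    missing <- setdiff(labels, pos$label)
    if (length(missing) > 0L) {
      stop("unknown electrode label(s): ", paste(missing, collapse = ", "),
           "; supply positions explicitly for non-10-20 sites")
    }
    pos <- pos[match(labels, pos$label), , drop = FALSE]
    rownames(pos) <- NULL
  }
  pos
}

#' @rdname montage_1020
#' @export
waveguard32_labels <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz", "C4", "T8", "M2",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "POz", "O1", "Oz", "O2")
}

# Unit vector from inclination (degrees from vertex) and azimuth
# (degrees clockwise from anterior midline when seen from above;
# negative = left hemisphere).
sph_vec <- function(inc, az) {
  inc <- inc * pi / 180
  az <- az * pi / 180
  c(x = sin(inc) * sin(az), y = sin(inc) * cos(az), z = cos(inc))
}

# Great-circle (slerp) interpolation between two unit vectors.
slerp <- function(p, q, t) {
  omega <- acos(max(-1, min(1, sum(p * q))))
  if (omega < 1e-12) return(p)
  (sin((1 - t) * omega) * p + sin(t * omega) * q) / sin(omega)
}

montage_positions <- function() {
  v <- list()
  # Sagittal midline: 10% arc steps of the nasion-inion great circle.
  v$Fpz <- sph_vec(72, 0);  v$Fz <- sph_vec(36, 0);  v$Cz <- sph_vec(0, 0)
  v$Pz <- sph_vec(36, 180); v$POz <- sph_vec(54, 180); v$Oz <- sph_vec(72, 180)
  # Outer (10%) ring, 18-degree steps around the head circumference.
  ring <- c(Fp1 = -18, Fp2 = 18, F7 = -54, F8 = 54, T7 = -90, T8 = 90,
            P7 = -126, P8 = 126, O1 = -162, O2 = 162)
  for (lab in names(ring)) v[[lab]] <- sph_vec(72, ring[[lab]])
  # Coronal rows: fractions along the arc from the midline site to the
  # outer-ring site of the same row (the 10-10 construction).
  v$F3 <- slerp(v$Fz, v$F7, 0.5);  v$F4 <- slerp(v$Fz, v$F8, 0.5)
  v$C3 <- slerp(v$Cz, v$T7, 0.5);  v$C4 <- slerp(v$Cz, v$T8, 0.5)
  v$P3 <- slerp(v$Pz, v$P7, 0.5);  v$P4 <- slerp(v$Pz, v$P8, 0.5)
  # FC/CP rows live on arcs between intermediate midline points and the
  # mid-temporal ring sites FT7/8, TP7/8.
  fcz <- sph_vec(18, 0); cpz <- sph_vec(18, 180)
  ft7 <- sph_vec(72, -72); ft8 <- sph_vec(72, 72)
  tp7 <- sph_vec(72, -108); tp8 <- sph_vec(72, 108)
  v$FC1 <- slerp(fcz, ft7, 0.25); v$FC2 <- slerp(fcz, ft8, 0.25)
  v$FC5 <- slerp(fcz, ft7, 0.75); v$FC6 <- slerp(fcz, ft8, 0.75)
  v$CP1 <- slerp(cpz, tp7, 0.25); v$CP2 <- slerp(cpz, tp8, 0.25)
  v$CP5 <- slerp(cpz, tp7, 0.75); v$CP6 <- slerp(cpz, tp8, 0.75)
  # Mastoids: below the ring, under T7/T8.
  v$M1 <- sph_vec(108, -95); v$M2 <- sph_vec(108, 95)

  labs <- waveguard32_labels()
  mat <- t(vapply(v[labs], identity, numeric(3)))
  inc <- acos(pmax(-1, pmin(1, mat[, "z"])))
  az <- atan2(mat[, "x"], mat[, "y"])
  r <- 0.8 * inc / (72 * pi / 180)  # vertex-centred azimuthal equidistant
  data.frame(label = labs,
             x = mat[, "x"], y = mat[, "y"], z = mat[, "z"],
             px = r * sin(az), py = r * cos(az),
             row.names = NULL, stringsAsFactors = FALSE)
}
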