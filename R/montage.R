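#' Standard 64-channel 10-20 scalp montage
#'
#' Builds the 64-electrode extended 10-20 montage used throughout the package
#' (BioSemi-style label set). Positions are unit vectors on a spherical head
#' model (x = right, y = anterior, z = superior), constructed geometrically:
#' midline electrodes lie on the nasion-inion great circle at 18-degree steps
#' from the vertex, the outer 10% ring lies 72 degrees from the vertex at
#' 18-degree azimuthal steps, and intermediate electrodes are placed by
#' spherical interpolation along the coronal arcs joining midline and ring
#' electrodes, following the 10-10 subdivision. P9/P10 and Iz sit on the
#' 90-degree circle. The result is an idealized but geometrically faithful
#' layout adequate for neighborhood graphs, spherical-spline interpolation and
#' synthetic scalp topographies.
#'
#' @return A data.frame with columns `label`, `x`, `y`, `z` (64 rows).
#' @export
#' @examples
#' m <- montage_biosemi64()
#' stopifnot(nrow(m) == 64, all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 1) < 1e-12))
montage_biosemi64 <- function() {
  # unit vector at inclination `incl` (deg from vertex) and azimuth `az`
  # (deg from anterior midline, positive toward the left ear)
  pt <- function(incl, az) {
    ir <- incl * pi / 180
    ar <- az * pi / 180
    c(x = -sin(ir) * sin(ar), y = sin(ir) * cos(ar), z = cos(ir))
  }
  slerp <- function(a, b, f) {
    om <- acos(max(-1, min(1, sum(a * b))))
    if (om < 1e-12) return(a)
    (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
  }
  rows <- list()
  add <- function(label, v) rows[[label]] <<- v

  # midline, nasion-inion arc (18-degree steps from Cz)
  mid <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
           CPz = -18, Pz = -36, POz = -54, Oz = -72, Iz = -90)
  for (lab in names(mid)) {
    a <- mid[[lab]]
    add(lab, pt(abs(a), if (a >= 0) 0 else 180))
  }
  # outer 10% ring: 72 degrees from vertex, azimuth steps of 18 degrees
  ring <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
            TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  for (lab in names(ring)) add(lab, pt(72, ring[[lab]]))
  # coronal arcs: fractions along the great-circle arc midline -> outer ring
  arcs <- list(
    list(mid = "Fz",  ring = "F7",  labs = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    list(mid = "FCz", ring = "FT7", labs = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    list(mid = "Cz",  ring = "T7",  labs = c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    list(mid = "CPz", ring = "TP7", labs = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    list(mid = "Pz",  ring = "P7",  labs = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    list(mid = "AFz", ring = "AF7", labs = c(AF3 = 0.5)),
    list(mid = "POz", ring = "PO7", labs = c(PO3 = 0.5))
  )
  for (arc in arcs) {
    for (lab in names(arc$labs))
      add(lab, slerp(rows[[arc$mid]], rows[[arc$ring]], arc$labs[[lab]]))
  }
  add("P9", pt(90, 126))
  # mirror the left hemisphere to the right (negate x)
  left <- c(names(ring), "P9",
            unlist(lapply(arcs, function(a) names(a$labs))))
  right_of <- c(Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8", T7 = "T8",
                TP7 = "TP8", P7 = "P8", PO7 = "PO8", O1 = "O2", P9 = "P10",
                F1 = "F2", F3 = "F4", F5 = "F6", FC1 = "FC2", FC3 = "FC4",
                FC5 = "FC6", C1 = "C2", C3 = "C4", C5 = "C6", CP1 = "CP2",
                CP3 = "CP4", CP5 = "CP6", P1 = "P2", P3 = "P4", P5 = "P6",
                AF3 = "AF4", PO3 = "PO4")
  for (lab in left) {
    v <- rows[[lab]]
    add(right_of[[lab]], c(-v[1], v[2], v[3]))
  }
  labs <- names(rows)
  out <- data.frame(label = labs,
                    x = vapply(rows, `[[`, 0, 1),
                    y = vapply(rows, `[[`, 0, 2),
                    z = vapply(rows, `[[`, 0, 3),
                    row.names = NULL, stringsAsFactors = FALSE)
  # canonical order: left-to-right within front-to-back rows is not needed
  # downstream; sort alphabetically-stable by label for reproducibility
  out[order(out$label), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Pairwise chord distances between montage electrodes
#' @param montage data.frame from [montage_biosemi64()] (or same shape)
#' @return symmetric matrix of Euclidean (chord) distances, unit-sphere scale
#' @export
montage_distances <- function(montage) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- list(montage$label, montage$label)
  d
}
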