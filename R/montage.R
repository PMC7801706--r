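#' Standard 10-20 montage coordinates for the 19-channel layout
#'
#' Two-dimensional schematic electrode positions (top view, unit head radius)
#' for the 19 channels of the International 10-20 system used throughout the
#' package. `x` increases to the subject's right, `y` toward the front.
#'
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' head(montage_1020())
montage_1020 <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8",
                "C3", "C4", "Cz", "P3", "P4", "Pz", "O1", "O2",
                "T3", "T4", "T5", "T6"),
    x = c(-0.309, 0.309, -0.400, 0.400, 0.000, -0.809, 0.809,
          -0.500, 0.500, 0.000, -0.400, 0.400, 0.000, -0.309, 0.309,
          -1.000, 1.000, -0.809, 0.809),
    y = c(0.951, 0.951, 0.520, 0.520, 0.500, 0.588, 0.588,
          0.000, 0.000, 0.000, -0.520, -0.520, -0.500, -0.951, -0.951,
          0.000, 0.000, -0.588, -0.588),
    stringsAsFactors = FALSE
  )
}

# Generic circular layout for channel counts other than 19.
circular_montage <- function(n_channels) {
  ang <- seq(0, 2 * pi, length.out = n_channels + 1L)[seq_len(n_channels)]
  data.frame(
    channel = paste0("ch", seq_len(n_channels)),
    x = cos(ang), y = sin(ang),
    stringsAsFactors = FALSE
  )
}

check_montage <- function(montage) {
  stopifnot(is.data.frame(montage), all(c("channel", "x", "y") %in% names(montage)))
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  diag(d) <- Inf
  if (min(d) < 1e-6) stop("invalid montage: coincident electrodes", call. = FALSE)
  invisible(montage)
}

#' Canonical archetype topographies on a montage
#'
#' Builds the four canonical orientation templates used to label microstate
#' maps with the archetype taxonomy: type A a left-right dominant diagonal
#' (left-posterior to right-frontal), type B its mirror (right-left), type C
#' an anterior-posterior gradient, and type D a focal fronto-central maximum.
#' Each template is a smooth field over the electrode positions, zero-mean
#' across channels and unit-norm (average-reference consistent).
#'
#' @param montage Data.frame with `channel`, `x`, `y` columns.
#' @return A channels x 4 matrix with columns named `A`..`D`.
#' @export
canonical_templates <- function(montage = montage_1020()) {
  check_montage(montage)
  x <- montage$x
  y <- montage$y
  # A/B axes tilted 30 degrees off the left-right axis so the left-right
  # component dominates the anterior-posterior one.
  a <- cos(pi / 6) * x + sin(pi / 6) * y
  b <- -cos(pi / 6) * x + sin(pi / 6) * y
  cc <- y
  d <- exp(-((x - 0)^2 + (y - 0.25)^2) / (2 * 0.35^2))
  tpl <- cbind(A = a, B = b, C = cc, D = d)
  tpl <- sweep(tpl, 2L, colMeans(tpl), "-")
  tpl <- unit_norm_cols(tpl)
  rownames(tpl) <- montage$channel
  tpl
}
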