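## H&E stain model.
##
## The synthetic renderer and the unmixer share one fixed two-stain linear
## model in optical density (Beer-Lambert): OD = -log10(transmission),
## OD = C_h * v_h + C_e * v_e, with Ruifrok-style unit vectors for
## hematoxylin and eosin.  Because the mixing is known exactly, stain
## separation can be validated against ground truth concentrations.

#' H&E stain matrix
#'
#' Columns are unit optical-density vectors for hematoxylin, eosin and a
#' residual direction orthogonal to both.  Fixed; shared by the synthetic
#' renderer and [separate_stains()].
#'
#' @return a 3 x 3 numeric matrix with columns `hematoxylin`, `eosin`,
#'   `residual`.
#' @export
he_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.070, 0.990, 0.105)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  m <- cbind(hematoxylin = h, eosin = e, residual = r)
  rownames(m) <- c("R", "G", "B")
  m
}

## Render an RGB image (h x w x 3, [0, 1]) from per-pixel stain
## concentrations, with 8-bit quantization to match TIFF round-trips.
rgb_from_concentrations <- function(H, E, quantize = TRUE) {
  m <- he_stain_matrix()
  img <- array(0, dim = c(nrow(H), ncol(H), 3L))
  for (ch in 1:3) {
    od <- H * m[ch, "hematoxylin"] + E * m[ch, "eosin"]
    img[, , ch] <- 10^(-od)
  }
  img <- clamp01(img)
  if (quantize) img <- round(img * 255) / 255
  img
}

#' Separate hematoxylin and eosin channels
#'
#' Optical-density unmixing of an RGB image against the fixed stain matrix
#' of [he_stain_matrix()].  Hematoxylin and eosin concentrations are
#' clipped at zero; the residual channel is returned signed.
#'
#' @param image RGB array (`height x width x 3`) with values in `[0, 1]`.
#' @return an object of class `stain_channels`: a list with matrices
#'   `hematoxylin`, `eosin`, `residual`, each of the image's spatial
#'   dimensions.
#' @export
#' @examples
#' img <- array(1, dim = c(8, 8, 3))        # pure white: no stain
#' st <- separate_stains(img)
#' max(st$hematoxylin)
separate_stains <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  if (all(image < 1 / 255)) {
    abort("cannot unmix an all-black (fully saturated) image: optical density is unbounded")
  }
  eps <- 1 / 512                      # guards the log at full saturation
  m <- he_stain_matrix()
  minv <- solve(m)
  d <- dim(image)
  od <- matrix(0, nrow = 3, ncol = d[1] * d[2])
  for (ch in 1:3) od[ch, ] <- -log10(pmax(image[, , ch], eps))
  conc <- minv %*% od
  shape <- function(v, clip) {
    mtx <- matrix(v, nrow = d[1], ncol = d[2])
    if (clip) mtx[mtx < 0] <- 0
    mtx
  }
  structure(
    list(
      hematoxylin = shape(conc[1, ], clip = TRUE),
      eosin       = shape(conc[2, ], clip = TRUE),
      residual    = shape(conc[3, ], clip = FALSE)
    ),
    class = "stain_channels"
  )
}

#' @export
print.stain_channels <- function(x, ...) {
  d <- dim(x$hematoxylin)
  cat(sprintf("<stain_channels> %d x %d px; max H = %.2f, max E = %.2f OD\n",
              d[2], d[1], max(x$hematoxylin), max(x$eosin)))
  invisible(x)
}
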