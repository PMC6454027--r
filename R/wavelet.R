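#' Haar analysis filter pair
#'
#' Returns the orthonormal Haar finite-impulse-response filter pair: the
#' low-pass filter `lo = (1, 1)/sqrt(2)` and the high-pass filter
#' `hi = (1, -1)/sqrt(2)`. The orthonormal normalization (rather than an
#' explicit `1/sqrt(MN)` prefactor) is used throughout: downstream
#' dissimilarities are Pearson correlations, which are invariant to global
#' scaling, and orthonormality yields exact energy conservation and perfect
#' reconstruction on even-sided inputs.
#'
#' @return A list with numeric components `lo` and `hi`, each of length 2.
#' @export
#' @examples
#' f <- haar_filters()
#' sum(f$lo^2) # 1
#' sum(f$lo * f$hi) # 0
haar_filters <- function() {
  list(lo = c(1, 1) / sqrt(2), hi = c(1, -1) / sqrt(2))
}

# One analysis step along the row index (i.e. filtering down each column),
# with symmetric half-sample padding for odd row counts: the last row is
# repeated, giving output length floor((n + 1) / 2). This boundary rule
# reproduces the 175 -> 88 -> 44 -> 22 -> 11 -> 6 side-length chain.
haar_analysis_rows <- function(x) {
  n <- nrow(x)
  if (n %% 2L == 1L) x <- rbind(x, x[n, , drop = FALSE])
  odd <- seq(1L, nrow(x), by = 2L)
  list(
    lo = (x[odd, , drop = FALSE] + x[odd + 1L, , drop = FALSE]) / sqrt(2),
    hi = (x[odd, , drop = FALSE] - x[odd + 1L, , drop = FALSE]) / sqrt(2)
  )
}

#' Convert a raster image to a grayscale intensity grid in [0, 1]
#'
#' Accepts either a numeric matrix (single-channel image) or a
#' rows x cols x 3 array (RGB). RGB images are converted with BT.601
#' luminance weights (0.299, 0.587, 0.114). Inputs on an 8-bit scale
#' (maximum value > 1) are rescaled by 1/255.
#'
#' @param image Numeric matrix or rows x cols x 3 numeric array.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
#' @examples
#' to_grayscale(matrix(128, 4, 4)) # 128/255 everywhere
to_grayscale <- function(image) {
  if (!is.numeric(image) || !all(is.finite(image))) {
    stopf("image must be numeric with finite values")
  }
  if (is.matrix(image)) {
    g <- image
  } else if (is.array(image) && length(dim(image)) == 3L) {
    nc <- dim(image)[3L]
    if (nc != 3L) {
      stopf("unsupported channel count: %d (expected 1 or 3)", nc)
    }
    g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  } else {
    stopf("image must be a matrix or a rows x cols x 3 array")
  }
  if (max(g) > 1) g <- g / 255
  g
}

#' One level of 2D Haar wavelet decomposition
#'
#' Decomposes a 2D grid into four sub-bands by separable filtering and
#' dyadic downsampling: approximation `A` (low-pass along both axes),
#' horizontal detail `H` (high-pass across rows, low-pass across columns;
#' responds maximally to horizontal stripes), vertical detail `V`
#' (low-pass across rows, high-pass across columns), and diagonal detail
#' `D` (high-pass along both axes). Odd side lengths are handled by
#' symmetric half-sample padding; each output side is
#' `floor((n + 1) / 2)`.
#'
#' @param input Numeric matrix, at least 2 x 2, finite.
#' @param level Integer label attached to the result (recursion depth).
#' @return An object of class `quad_bands`: a list with `level` and the
#'   four coefficient matrices `A`, `H`, `V`, `D` (all the same shape).
#' @export
#' @examples
#' qb <- dwt2_level(matrix(c(1, 3, 2, 4), 2, 2))
#' qb$A # 5
#' qb$H # -2
dwt2_level <- function(input, level = 1L) {
  if (!is.matrix(input) || !is.numeric(input)) stopf("input must be a numeric matrix")
  if (!all(is.finite(input))) stopf("input contains non-finite values")
  if (nrow(input) < 2L || ncol(input) < 2L) {
    stopf(
      "input is %dx%d; each dimension must be at least 2",
      nrow(input), ncol(input)
    )
  }
  rows <- haar_analysis_rows(input)
  # second pass runs along the column index via transposition
  lo_r <- haar_analysis_rows(t(rows$lo))
  hi_r <- haar_analysis_rows(t(rows$hi))
  structure(
    list(
      level = as.integer(level),
      A = t(lo_r$lo),
      H = t(hi_r$lo),
      V = t(lo_r$hi),
      D = t(hi_r$hi)
    ),
    class = "quad_bands"
  )
}

#' Inverse of one 2D Haar decomposition level
#'
#' Reconstructs an even-sided input from its four sub-bands. Only exact for
#' inputs whose side lengths were even (no padding was involved).
#'
#' @param qb A `quad_bands` object from [dwt2_level()].
#' @return The reconstructed numeric matrix.
#' @export
idwt2_level <- function(qb) {
  stopifnot(inherits(qb, "quad_bands"))
  synth_rows <- function(lo, hi) {
    out <- matrix(0, nrow(lo) * 2L, ncol(lo))
    odd <- seq(1L, nrow(out), by = 2L)
    out[odd, ] <- (lo + hi) / sqrt(2)
    out[odd + 1L, ] <- (lo - hi) / sqrt(2)
    out
  }
  lo_rows <- t(synth_rows(t(qb$A), t(qb$V)))
  hi_rows <- t(synth_rows(t(qb$H), t(qb$D)))
  synth_rows(lo_rows, hi_rows)
}

#' Multilevel 2D Haar decomposition
#'
#' Applies [dwt2_level()] recursively: the approximation band of level
#' `j - 1` is the input to level `j` (level-0 approximation is the image
#' itself).
#'
#' @param image Numeric matrix (a grayscale stimulus).
#' @param levels Number of decomposition levels (>= 1).
#' @return A list of `levels` [quad_bands][dwt2_level] objects.
#' @export
#' @examples
#' pyr <- multilevel_decompose(matrix(rnorm(64^2), 64, 64), levels = 5)
#' vapply(pyr, function(q) nrow(q$A), integer(1)) # 32 16 8 4 2
multilevel_decompose <- function(image, levels) {
  if (!is_count(levels)) stopf("levels must be a positive integer")
  out <- vector("list", levels)
  cur <- image
  for (j in seq_len(levels)) {
    if (nrow(cur) < 2L || ncol(cur) < 2L) {
      stopf(
        "image too small for %d levels: level %d input is %dx%d (needs at least 2x2)",
        levels, j, nrow(cur), ncol(cur)
      )
    }
    out[[j]] <- dwt2_level(cur, level = j)
    cur <- out[[j]]$A
  }
  out
}

# Canonical descriptor manifest: ids W1..W(5*levels) in level-major order
# with bands A, H, V, D, ALL within each level.
descriptor_manifest <- function(levels = 5L) {
  bands <- c("A", "H", "V", "D", "ALL")
  data.frame(
    id = paste0("W", seq_len(5L * levels)),
    level = rep(seq_len(levels), each = 5L),
    band = rep(bands, levels),
    stringsAsFactors = FALSE
  )
}

#' Build the wavelet descriptor set for a collection of stimuli
#'
#' For each stimulus and each decomposition level, produces five flattened
#' descriptor vectors: the approximation `A`, the oriented details `H`,
#' `V`, `D`, and `ALL` — the concatenation of H, V and D (in that order).
#' With the default 5 levels this yields 25 descriptors per stimulus,
#' labelled `W1` ... `W25` in level-major order (A, H, V, D, ALL within
#' each level). Flattening is row-major and identical across stimuli, so
#' descriptor RDMs are well-defined.
#'
#' @param images List of numeric matrices, all of the same shape.
#' @param levels Number of decomposition levels (default 5).
#' @return An object of class `wavelet_descriptor_set`: a list with
#'   `manifest` (data.frame: id, level, band, length) and `vectors`, a
#'   named list mapping each descriptor id to an n_stimuli x length
#'   matrix whose row i is stimulus i's descriptor.
#' @export
build_descriptors <- function(images, levels = 5L) {
  if (!length(images)) stopf("need at least one image")
  shp <- dim(images[[1L]])
  same <- vapply(images, function(im) identical(dim(im), shp), logical(1))
  if (!all(same)) stopf("all images must share the same shape")
  pyrs <- lapply(images, multilevel_decompose, levels = levels)
  man <- descriptor_manifest(levels)
  flatten <- function(m) as.vector(t(m)) # row-major
  vecs <- vector("list", nrow(man))
  names(vecs) <- man$id
  lens <- integer(nrow(man))
  for (k in seq_len(nrow(man))) {
    lev <- man$level[k]
    band <- man$band[k]
    get_vec <- function(pyr) {
      qb <- pyr[[lev]]
      if (band == "ALL") {
        c(flatten(qb$H), flatten(qb$V), flatten(qb$D))
      } else {
        flatten(qb[[band]])
      }
    }
    rows <- lapply(pyrs, get_vec)
    vecs[[k]] <- do.call(rbind, rows)
    lens[k] <- ncol(vecs[[k]])
  }
  man$length <- lens
  structure(
    list(manifest = man, vectors = vecs, levels = as.integer(levels)),
    class = "wavelet_descriptor_set"
  )
}

#' @export
print.wavelet_descriptor_set <- function(x, ...) {
  cat(sprintf(
    "<wavelet_descriptor_set> %d descriptors x %d stimuli (%d levels)\n",
    nrow(x$manifest), nrow(x$vectors[[1L]]), x$levels
  ))
  invisible(x)
}

#' Detail-band energies of an image at one decomposition level
#'
#' Convenience used to verify the oriented edge content of generated
#' stimuli: returns the summed squared coefficients of the H, V and D
#' bands at the requested level.
#'
#' @param image Numeric matrix.
#' @param level Decomposition level (default 1).
#' @return Named numeric vector `c(H = , V = , D = )`.
#' @export
band_energies <- function(image, level = 1L) {
  pyr <- multilevel_decompose(image, levels = level)
  qb <- pyr[[level]]
  c(H = sum(qb$H^2), V = sum(qb$V^2), D = sum(qb$D^2))
}
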