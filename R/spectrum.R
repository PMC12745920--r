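#' Two-dimensional site frequency spectrum
#'
#' Container for a joint site frequency spectrum (JSFS) of two population
#' samples of `n1` and `n2` haploid chromosomes. Entry `(i, j)` (0-based)
#' holds the number of sites (or, for model spectra, the expected density per
#' unit theta) at which the derived -- or, for folded spectra, minor --
#' allele was seen `i` times in population 1 and `j` times in population 2.
#' The "absent everywhere" and "fixed everywhere" corners carry no
#' polymorphism information and are always masked; masked entries are ignored
#' by all likelihood and mass computations.
#'
#' @param data numeric `(n1+1) x (n2+1)` matrix of non-negative entries.
#' @param folded logical; is the spectrum folded (minor-allele orientation)?
#' @param mask optional logical matrix of the same shape, `TRUE` = masked.
#'   The corners (and, for folded spectra, entries beyond the fold line) are
#'   masked in addition to anything supplied here.
#' @param pop_labels character vector of length 2 naming the two populations.
#' @return An object of class `refugia_spectrum`.
#' @export
spectrum2d <- function(data, folded = FALSE, mask = NULL,
                       pop_labels = c("pop1", "pop2")) {
  data <- as.matrix(data)
  n1 <- nrow(data) - 1L
  n2 <- ncol(data) - 1L
  if (n1 < 1L || n2 < 1L) stop("spectrum must be at least 2 x 2")
  if (any(!is.finite(data))) stop("spectrum entries must be finite")
  if (is.null(mask)) {
    mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(data))) stop("mask shape must match data shape")
    mask <- mask | is.na(mask)
  }
  mask[1L, 1L] <- TRUE
  mask[n1 + 1L, n2 + 1L] <- TRUE
  if (folded) {
    tot <- outer(0:n1, 0:n2, `+`)
    mask[tot > (n1 + n2) / 2] <- TRUE
  }
  if (any(data[!mask] < 0)) stop("unmasked spectrum entries must be >= 0")
  structure(
    list(data = data, mask = mask, n1 = n1, n2 = n2, folded = folded,
         pop_labels = pop_labels),
    class = "refugia_spectrum"
  )
}

#' @export
print.refugia_spectrum <- function(x, ...) {
  cat(sprintf("2D-SFS: (%d+1) x (%d+1), %s, pops %s/%s\n", x$n1, x$n2,
              if (x$folded) "folded" else "unfolded",
              x$pop_labels[1], x$pop_labels[2]))
  cat(sprintf("unmasked mass: %.6g over %d entries\n",
              spectrum_mass(x), sum(!x$mask)))
  invisible(x)
}

#' Total mass of the unmasked spectrum entries
#' @param spec a `refugia_spectrum`.
#' @export
spectrum_mass <- function(spec) sum(spec$data[!spec$mask])

#' Transpose a spectrum (swap the two populations)
#' @param spec a `refugia_spectrum`.
#' @export
transpose_spectrum <- function(spec) {
  spectrum2d(t(spec$data), folded = spec$folded, mask = t(spec$mask),
             pop_labels = rev(spec$pop_labels))
}

# fold weights: 1 below the fold line, 0.5 on it, 0 above
fold_weights <- function(n1, n2) {
  tot <- outer(0:n1, 0:n2, `+`)
  w <- matrix(0, n1 + 1L, n2 + 1L)
  w[tot < (n1 + n2) / 2] <- 1
  w[tot == (n1 + n2) / 2] <- 0.5
  w
}

# apply minor-allele folding to a raw data array (no class bookkeeping)
fold_data <- function(data) {
  n1 <- nrow(data) - 1L
  n2 <- ncol(data) - 1L
  rev2 <- data[(n1 + 1L):1L, (n2 + 1L):1L, drop = FALSE]
  (data + rev2) * fold_weights(n1, n2)
}

#' Fold a spectrum over ancestral-state uncertainty
#'
#' Collapses complementary entries `(i, j)` and `(n1-i, n2-j)` so the
#' spectrum is indexed by the minor combined allele count; used when no
#' outgroup polarises ancestral states. Entries beyond the fold line are
#' masked; unmasked mass is conserved.
#'
#' @param spec an unfolded `refugia_spectrum`.
#' @export
fold_spectrum <- function(spec) {
  if (spec$folded) stop("spectrum is already folded")
  revmask <- spec$mask[(spec$n1 + 1L):1L, (spec$n2 + 1L):1L, drop = FALSE]
  spectrum2d(fold_data(spec$data), folded = TRUE, mask = spec$mask & revmask,
             pop_labels = spec$pop_labels)
}

# hypergeometric projection matrix: rows target counts 0..np, cols source 0..n
projection_matrix <- function(n, np) {
  outer(0:np, 0:n, function(ip, i) stats::dhyper(ip, i, n - i, np))
}

#' Down-project a spectrum to smaller sample sizes
#'
#' Hypergeometric resampling: `S'(i',j') = sum S(i,j) H(i'; i, n1, n1p)
#' H(j'; j, n2, n2p)`, the expected spectrum of a random subsample of `n1p`
#' and `n2p` chromosomes. Projection lets partially genotyped sites
#' contribute; mass that becomes monomorphic accumulates in the masked
#' corners. Projecting to the current sizes is the identity.
#'
#' @param spec a `refugia_spectrum`.
#' @param n1p,n2p target haploid sample sizes, `<=` the current sizes.
#' @export
project_spectrum <- function(spec, n1p, n2p) {
  if (n1p > spec$n1 || n2p > spec$n2) stop("cannot project upward")
  if (n1p < 1 || n2p < 1) stop("projection sizes must be >= 1")
  if (n1p == spec$n1 && n2p == spec$n2) return(spec)
  P1 <- projection_matrix(spec$n1, n1p)
  P2 <- projection_matrix(spec$n2, n2p)
  out <- P1 %*% spec$data %*% t(P2)
  if (spec$folded) out <- fold_data(out)
  spectrum2d(out, folded = spec$folded, pop_labels = spec$pop_labels)
}

#' Read / write the plain-text spectrum format
#'
#' Three lines: `"<n1+1> <n2+1> <folded|unfolded>"`, the row-major entries,
#' and the row-major mask bits (1 = masked).
#'
#' @param spec a `refugia_spectrum`.
#' @param path file path.
#' @rdname spectrum_io
#' @export
write_spectrum <- function(spec, path) {
  d <- t(spec$data)  # row-major: row index varies slowest
  m <- t(spec$mask) * 1L
  lines <- c(
    sprintf("%d %d %s", spec$n1 + 1L, spec$n2 + 1L,
            if (spec$folded) "folded" else "unfolded"),
    paste(format(as.vector(d), digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "),
    paste(as.vector(m), collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname spectrum_io
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  r1 <- as.integer(hdr[1])
  r2 <- as.integer(hdr[2])
  folded <- identical(hdr[3], "folded")
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  bits <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  if (length(vals) != r1 * r2 || length(bits) != r1 * r2)
    stop("spectrum file is inconsistent with its header")
  data <- matrix(vals, nrow = r1, ncol = r2, byrow = TRUE)
  mask <- matrix(bits == 1L, nrow = r1, ncol = r2, byrow = TRUE)
  spectrum2d(data, folded = folded, mask = mask)
}

#' @export
plot.refugia_spectrum <- function(x, log = TRUE, ...) {
  z <- x$data
  z[x$mask] <- NA
  if (log) z <- log10(z + min(z[z > 0 & !x$mask], na.rm = TRUE) * 1e-2)
  graphics::image(0:x$n1, 0:x$n2, z, xlab = x$pop_labels[1],
                  ylab = x$pop_labels[2], ...)
  invisible(x)
}
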