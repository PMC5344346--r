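#' @keywords internal
"_PACKAGE"

# cache for the filter/catalog tables shipped with the package
.dwtselect_env <- new.env(parent = emptyenv())

.load_table <- function(name) {
  if (is.null(.dwtselect_env[[name]])) {
    path <- system.file("extdata", paste0(name, ".csv"), package = "dwtselect",
                        mustWork = TRUE)
    .dwtselect_env[[name]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .dwtselect_env[[name]]
}

#' Catalog of the 54 candidate mother wavelets
#'
#' The candidate set spans seven families commonly used in wavelet-based EEG
#' analysis: Biorthogonal (15 members), Coiflets (5), Daubechies (10), Reverse
#' biorthogonal (15), Symlets (7), Discrete Meyer (1) and Haar (1).
#'
#' @return A data.frame with one row per mother wavelet and columns
#'   `wavelet` (member name, e.g. `"coif3"`), `family`, `filter_length`
#'   (number of taps of the decomposition filters) and `vanishing_moments`
#'   (of the analysis wavelet; `NA` for the discrete Meyer FIR approximation,
#'   whose underlying wavelet has no finite vanishing-moment count).
#' @export
#' @examples
#' cat54 <- wavelet_catalog()
#' table(cat54$family)
wavelet_catalog <- function() {
  .load_table("wavelet_catalog")
}

#' Decomposition and reconstruction filters of a catalog wavelet
#'
#' Decomposition filters are stored with the package; reconstruction filters
#' are derived through the quadrature-mirror relations
#' `rec_lo[n] = (-1)^(n+1) dec_hi[n]` and `rec_hi[n] = (-1)^n dec_lo[n]`.
#'
#' @param wavelet a member name from [wavelet_catalog()].
#' @return A list with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` (numeric
#'   vectors of equal length) and `length` (the filter length F).
#' @export
wavelet_filters <- function(wavelet) {
  stopifnot(is.character(wavelet), length(wavelet) == 1L)
  key <- paste0("filters_", wavelet)
  if (!is.null(.dwtselect_env[[key]])) return(.dwtselect_env[[key]])
  tab <- .load_table("wavelet_filters")
  rows <- tab[tab$wavelet == wavelet, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown wavelet '", wavelet, "'; see wavelet_catalog()")
  }
  dec_lo <- rows$value[rows$filter == "dec_lo"][order(rows$idx[rows$filter == "dec_lo"])]
  dec_hi <- rows$value[rows$filter == "dec_hi"][order(rows$idx[rows$filter == "dec_hi"])]
  n <- seq_along(dec_lo) - 1L
  out <- list(
    dec_lo = dec_lo,
    dec_hi = dec_hi,
    rec_lo = (-1)^(n + 1) * dec_hi,
    rec_hi = (-1)^n * dec_lo,
    length = length(dec_lo)
  )
  .dwtselect_env[[key]] <- out
  out
}

#' Maximum useful decomposition level
#'
#' The deepest dyadic level for a signal of `n` samples under a wavelet with
#' filter length `f`: `floor(log2(n / (f - 1)))`. Deeper levels would leave fewer
#' coefficients than filter taps, so the bands would be dominated by boundary
#' extension.
#'
#' @param n signal length in samples (`n >= f`).
#' @param f filter length in samples (`f >= 2`).
#' @return Integer level `>= 1`.
#' @export
#' @examples
#' max_decomposition_level(5120, 2)   # haar on a 20 s, 256 Hz segment -> 12
#' max_decomposition_level(5120, 102) # dmey -> 5
max_decomposition_level <- function(n, f) {
  stopifnot(length(n) == 1L, length(f) == 1L)
  if (!is.finite(n) || !is.finite(f) || f < 2) {
    stop("need finite n and filter length f >= 2")
  }
  if (n < f) stop("signal length n = ", n, " is shorter than the filter (", f, ")")
  lev <- floor(log2(n / (f - 1)))
  if (lev < 1) stop("no valid decomposition level for n = ", n, ", f = ", f)
  as.integer(lev)
}
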