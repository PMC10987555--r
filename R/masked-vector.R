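#' Per-bin vector with an exclusion mask
#'
#' Carries one real value per genomic bin together with a logical mask
#' (`TRUE` = excluded). Masked bins hold `NA` and are excluded from every
#' downstream aggregate; the mask propagates through arithmetic as the union
#' of the operands' masks.
#'
#' @param values Numeric vector.
#' @param mask Logical vector of the same length; `TRUE` marks excluded bins.
#'   Non-finite values are masked automatically.
#' @return An object of class `masked_vector` with elements `values` (masked
#'   entries set to `NA`) and `mask`.
#' @export
masked_vector <- function(values, mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  mask <- as.logical(mask) | !is.finite(values)
  if (length(mask) != length(values))
    stop("mask length must match values length")
  values[mask] <- NA_real_
  structure(list(values = values, mask = mask), class = "masked_vector")
}

#' @export
length.masked_vector <- function(x) length(x$values)

#' @export
print.masked_vector <- function(x, ...) {
  cat(sprintf("masked_vector: %d bins, %d masked\n",
              length(x$values), sum(x$mask)))
  invisible(x)
}

#' @export
Ops.masked_vector <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop("operation '", .Generic, "' not defined for masked_vector")
  v1 <- if (inherits(e1, "masked_vector")) e1$values else as.numeric(e1)
  v2 <- if (missing(e2)) NULL
        else if (inherits(e2, "masked_vector")) e2$values else as.numeric(e2)
  m1 <- if (inherits(e1, "masked_vector")) e1$mask else FALSE
  m2 <- if (missing(e2) || !inherits(e2, "masked_vector")) FALSE else e2$mask
  if (missing(e2)) {
    out <- get(.Generic)(v1)
    return(masked_vector(out, m1))
  }
  out <- get(.Generic)(v1, v2)
  masked_vector(out, m1 | m2)
}

#' Extract values from a masked vector
#' @param x A [masked_vector()].
#' @param drop_masked If `TRUE`, return only unmasked values; otherwise return
#'   the full-length vector with `NA` at masked bins.
#' @return Numeric vector.
#' @export
mv_values <- function(x, drop_masked = FALSE) {
  stopifnot(inherits(x, "masked_vector"))
  if (drop_masked) x$values[!x$mask] else x$values
}
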