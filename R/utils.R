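#' Round half away from zero
#'
#' Report tables in single-case movement-behavior studies are conventionally
#' printed to one decimal with halves rounded away from zero, which differs
#' from [base::round()]'s round-half-to-even rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25, 1.05), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # nudge by a relative epsilon so that values printed as x.x5 (stored just
  # below the midpoint in binary) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sample() treats a length-1 numeric as 1:n; these wrappers always sample
# from the elements of x
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Number of distinct permutations of a multiset: n! / prod(m_k!)
multiset_count <- function(x) {
  counts <- table(x)
  n <- exp(lgamma(length(x) + 1) - sum(lgamma(counts + 1)))
  if (n < 2^52) round(n) else n
}

# environment-level cache: enumerating the same multiset repeatedly is the
# common case in simulation studies
.perm_cache <- new.env(parent = emptyenv())

#' Enumerate distinct permutations of a multiset
#'
#' Generates every distinct ordering of the values in `x` exactly once, the
#' assignment space of the within-set (Wampold-Worsham) randomization scheme.
#'
#' @param x Vector of values (duplicates allowed).
#' @param limit Maximum number of permutations to materialize; exceeding it is
#'   an error (use a Monte Carlo sampler instead).
#' @return A matrix with one row per distinct permutation.
#' @export
multiset_permutations <- function(x, limit = 1e6) {
  n_perm <- multiset_count(x)
  if (n_perm > limit) {
    abort(sprintf(
      "multiset has %.0f distinct permutations, above the limit of %.0f",
      n_perm, limit
    ))
  }
  key <- paste(sort(x), collapse = "\r")
  cached <- .perm_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  n <- length(x)
  out <- matrix(x[0], nrow = n_perm, ncol = n)
  row <- 0L
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      row <<- row + 1L
      out[row, ] <<- prefix
      return(invisible(NULL))
    }
    for (v in unique(remaining)) {
      idx <- match(v, remaining)
      rec(c(prefix, v), remaining[-idx])
    }
  }
  rec(x[0], sort(x))
  if (n_perm <= 50000) .perm_cache[[key]] <- out
  out
}
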