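#' @importFrom rlang .data abort warn
#' @importFrom stats median quantile rnorm rchisq runif setNames
NULL

# Canonical form for taxon labels: trim surrounding whitespace and treat
# spaces and underscores as equivalent. Matching is otherwise exact and
# case-sensitive.
norm_label <- function(x) {
  gsub(" ", "_", trimws(as.character(x)), fixed = TRUE)
}

stop_phybite <- function(msg, class = "phybite_error") {
  rlang::abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_phybite(sprintf("`%s` must be finite and numeric.", name))
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    stop_phybite(sprintf(
      "`%s` must lie in %s%s, %s].",
      name, if (strict_lower) "(" else "[", format(lower), format(upper)
    ))
  }
  invisible(x)
}

require_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_phybite(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Small deterministic string hash (32-bit, for per-fold seed derivation and
# config fingerprints); not cryptographic.
string_hash32 <- function(x) {
  ints <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 5381
  for (i in ints) {
    # products stay below 2^53, so the arithmetic is exact in doubles
    h <- (h * 131 + i) %% 2147483629
  }
  as.integer(h)
}

# Derive a child seed below 2^31 from a master seed and a tag.
derive_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 48271 + string_hash32(as.character(tag))) %%
               2147483629)
}
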