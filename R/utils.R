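# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All generators route through this so a
# fixture is a pure function of its spec.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

relmeta_stop <- function(fmt, ..., class = "relmeta_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x)
}

# Labels are stored without the leading underscore ("rlnCtfMaxResolution").
# Queries may come with or without the underscore and/or the "rln" prefix;
# matching is case-sensitive per the STAR convention.
label_candidates <- function(query) {
  q <- sub("^_", "", query)
  unique(c(q, paste0("rln", q)))
}

resolve_label <- function(labels, query, context = "table") {
  for (cand in label_candidates(query)) {
    if (cand %in% labels) return(cand)
  }
  relmeta_stop(
    "label '%s' not found in %s; available labels: %s",
    query, context, paste(labels, collapse = ", "),
    class = "relmeta_lookup_error"
  )
}

# Fixed-precision rendering used by the STAR writer: 6 decimal places in
# fixed notation for moderate magnitudes, scientific otherwise. Stable under
# write -> parse -> write.
format_real <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) {
      out[i] <- "nan"
    } else if (v == 0 || (abs(v) >= 1e-4 && abs(v) < 1e7)) {
      out[i] <- sprintf("%.6f", v)
    } else {
      out[i] <- sprintf("%.6e", v)
    }
  }
  out
}

int_pattern <- "^[+-]?[0-9]+$"
real_pattern <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

looks_integer <- function(s) grepl(int_pattern, s)
looks_real <- function(s) grepl(real_pattern, s) | s %in% c("nan", "NaN", "inf", "-inf")

# Type a character vector of STAR tokens: all-integer -> integer, all-real ->
# double, else left as text. Mirrors RELION's untyped convention.
type_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  if (all(looks_integer(tokens))) {
    suppressWarnings(v <- as.integer(tokens))
    if (!anyNA(v)) return(v)
    return(as.numeric(tokens))
  }
  if (all(looks_real(tokens))) return(as.numeric(tokens))
  tokens
}

format_scalar <- function(v) {
  if (is.character(v)) {
    ifelse(grepl("[[:space:]]", v) | v == "", sprintf("\"%s\"", v), v)
  } else if (is.integer(v)) {
    sprintf("%d", v)
  } else {
    format_real(as.numeric(v))
  }
}
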