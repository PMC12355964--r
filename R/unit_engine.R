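# Unit parsing and canonicalization.
#
# Turnover numbers are canonicalized to per-second (s^-1), Michaelis constants
# to molar (M). Parsing flags the two ambiguities that matter for curation:
# scientific notation (sign-of-exponent transcription risk) and confusable
# micro/milli prefix glyphs, where reading "m" for a mu (or vice versa) shifts
# the value by exactly a factor of 1000.

prefix_factors <- c(none = 1, m = 1e-3, "μ" = 1e-6, n = 1e-9, k = 1e3)

superscript_map <- c(
  "⁰" = "0", "¹" = "1", "²" = "2", "³" = "3",
  "⁴" = "4", "⁵" = "5", "⁶" = "6", "⁷" = "7",
  "⁸" = "8", "⁹" = "9", "⁻" = "-", "⁺" = "+"
)

# normalize exotic minus signs / superscripts so one regex family suffices
normalize_unit_text <- function(x) {
  x <- stringr::str_replace_all(x, "[−‐–—]", "-")
  for (i in seq_along(superscript_map)) {
    x <- gsub(names(superscript_map)[i], superscript_map[i], x, fixed = TRUE)
  }
  x
}

glyph_confusable <- c("m", "μ", "µ", "u")

parse_unit_token <- function(unit) {
  unit0 <- stringr::str_trim(unit)
  u <- normalize_unit_text(unit0)
  u <- stringr::str_replace_all(u, "\\s+", "")
  out <- list(prefix = "none", base_unit = "unknown", glyph_ambiguous = FALSE)
  if (!nzchar(u)) return(out)

  rate_sec <- "^(1/|/)?(s|sec)(\\^?-1)?$"
  rate_min <- "^(1/|/)?min(\\^?-1)?$"
  if (grepl(rate_sec, u) && (grepl("/", u) || grepl("-1", u))) {
    out$base_unit <- "per_second"; return(out)
  }
  if (grepl(rate_min, u) && (grepl("/", u) || grepl("-1", u))) {
    out$base_unit <- "per_minute"; return(out)
  }

  # concentration: optional prefix + M, or prefix + mol/L
  pm <- stringr::str_match(u, "^([munμµk]?)M$")
  if (!is.na(pm[1, 1])) {
    pfx <- pm[1, 2]
  } else {
    pm <- stringr::str_match(u, "^([munμµk]?)mol/[lL]$")
    pfx <- if (!is.na(pm[1, 1])) pm[1, 2] else NA_character_
  }
  if (!is.na(pfx)) {
    out$base_unit <- "molar"
    raw_pfx <- pfx
    if (!nzchar(pfx)) {
      out$prefix <- "none"
    } else {
      if (pfx %in% c("µ", "u")) pfx <- "μ"
      out$prefix <- pfx
    }
    out$glyph_ambiguous <- nzchar(raw_pfx) && raw_pfx %in% glyph_confusable
    return(out)
  }
  if (u %in% c("ratio", "-", "dimensionless")) {
    out$base_unit <- "dimensionless_ratio"
    return(out)
  }
  out
}

# Extract the leading numeric token (plain, e-notation, or mantissa x 10^k).
# Returns list(value, sci_notation, n_chars consumed) or NULL.
parse_numeric_token <- function(text) {
  t <- normalize_unit_text(text)
  t <- gsub("(?<=\\d),(?=\\d)", "", t, perl = TRUE)  # thousands separators
  t <- stringr::str_trim(t)
  num <- "[+-]?(?:\\d+\\.?\\d*|\\.\\d+)"
  # mantissa x 10^k
  m <- stringr::str_match(
    t, paste0("^(", num, ")\\s*[x×*·]\\s*10\\s*\\^?\\s*([+-]?\\d+)")
  )
  if (!is.na(m[1, 1])) {
    return(list(value = as.numeric(m[1, 2]) * 10^as.numeric(m[1, 3]),
                sci_notation = TRUE,
                rest = stringr::str_trim(substring(t, nchar(m[1, 1]) + 1L))))
  }
  m <- stringr::str_match(t, paste0("^(", num, ")[eE]([+-]?\\d+)"))
  if (!is.na(m[1, 1])) {
    return(list(value = as.numeric(m[1, 2]) * 10^as.numeric(m[1, 3]),
                sci_notation = TRUE,
                rest = stringr::str_trim(substring(t, nchar(m[1, 1]) + 1L))))
  }
  m <- stringr::str_match(t, paste0("^(", num, ")"))
  if (!is.na(m[1, 1])) {
    return(list(value = as.numeric(m[1, 1]), sci_notation = FALSE,
                rest = stringr::str_trim(substring(t, nchar(m[1, 1]) + 1L))))
  }
  NULL
}

#' Parse a quantity string with its unit dialect
#'
#' Recognizes rate dialects (`s^-1`, `s-1` with Unicode minus, `/s`, `1/s`,
#' `sec^-1`, `min^-1`, `/min`, `1/min`) and concentration dialects (`M` with
#' SI prefixes m / mu / n / k, the three micro glyph variants mu, micro sign
#' and latin `u`, and the `mol/L` spelling). Scientific notation
#' (e-notation, `x 10^k`, superscript exponents) is parsed at face value and
#' flagged. Unknown units leave `base_unit = "unknown"` with the value still
#' parsed; only a string with no numeric token is an error.
#'
#' @param text quantity string, e.g. `"5 μM"` or `"120 min^-1"`.
#' @param kind `"rate"` or `"concentration"`; selects the canonical target
#'   unit (s^-1 or M).
#' @return a list of class `quantity` with fields `value`, `prefix`,
#'   `base_unit`, `canonical_value`, `raw_text`, `sci_notation`,
#'   `glyph_ambiguous`.
#' @export
#' @examples
#' parse_quantity("120 min^-1", "rate")$canonical_value   # 2
#' parse_quantity("5 μM", "concentration")$canonical_value  # 5e-6
parse_quantity <- function(text, kind = c("rate", "concentration")) {
  kind <- match.arg(kind)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  tok <- parse_numeric_token(text)
  if (is.null(tok)) stop("no numeric token in quantity text: ", sQuote(text))
  unit <- parse_unit_token(tok$rest)
  q <- structure(list(
    value = tok$value,
    prefix = unit$prefix,
    base_unit = unit$base_unit,
    canonical_value = NA_real_,
    raw_text = text,
    sci_notation = tok$sci_notation,
    glyph_ambiguous = unit$glyph_ambiguous
  ), class = "quantity")
  q$canonical_value <- canonical_or_na(q, kind)
  q
}

canonical_or_na <- function(q, kind) {
  pf <- unname(prefix_factors[[q$prefix]])
  if (kind == "rate") {
    if (q$base_unit == "per_second") return(q$value * pf)
    if (q$base_unit == "per_minute") return(q$value * pf / 60)
    return(NA_real_)
  }
  if (q$base_unit == "molar") return(q$value * pf)
  NA_real_
}

#' Canonical value of a parsed quantity
#'
#' Returns the value in s^-1 (rates) or molar (concentrations). Swapping the
#' prefix between m and mu multiplies the result by exactly 10^3 or 10^-3.
#'
#' @param q a `quantity` from [parse_quantity()].
#' @param kind `"rate"` or `"concentration"`.
#' @return a number.
#' @export
canonicalize <- function(q, kind = c("rate", "concentration")) {
  kind <- match.arg(kind)
  if (q$base_unit == "unknown") {
    stop("cannot canonicalize quantity with unknown unit: ", sQuote(q$raw_text))
  }
  v <- canonical_or_na(q, kind)
  if (is.na(v)) {
    stop("unit ", sQuote(q$base_unit), " is not a ", kind, " unit: ",
         sQuote(q$raw_text))
  }
  v
}

#' @export
format.quantity <- function(x, ...) {
  unit <- switch(x$base_unit,
    per_second = "s^-1", per_minute = "min^-1",
    molar = paste0(if (x$prefix == "none") "" else x$prefix, "M"),
    dimensionless_ratio = "", unknown = ""
  )
  paste(format(x$value, scientific = FALSE, trim = TRUE, digits = 15), unit)
}

#' @export
print.quantity <- function(x, ...) {
  cat("<quantity>", format(x),
      sprintf("[canonical %g, sci=%s, glyph_ambiguous=%s]\n",
              x$canonical_value, x$sci_notation, x$glyph_ambiguous))
  invisible(x)
}

#' Base-10 logarithm of a canonical value
#'
#' @param canonical a strictly positive number (vectorized).
#' @return log10 of the input.
#' @export
log10_value <- function(canonical) {
  if (any(is.na(canonical)) || any(canonical <= 0)) {
    stop("log10_value requires strictly positive inputs")
  }
  log10(canonical)
}
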