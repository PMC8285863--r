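#' @importFrom rlang abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Smallest p-value representable on the -log10 axis; p = 0 is clamped here.
P_FLOOR <- 1e-300

#' Clamp zero p-values to a representable floor
#'
#' p-values of exactly zero (as printed by some GWAS/eQTL pipelines) cannot be
#' log-transformed; they are clamped to 1e-300 with a warning.
#'
#' @param p numeric vector of p-values.
#' @param what label used in the warning message.
#' @return `p` with zeros replaced by 1e-300.
#' @keywords internal
clamp_pvalues <- function(p, what = "p-value") {
  zero <- !is.na(p) & p == 0
  if (any(zero)) {
    warn(sprintf("%d %s(s) equal to 0 clamped to %g for log10 transforms",
                 sum(zero), what, P_FLOOR))
    p[zero] <- P_FLOOR
  }
  p
}

# Normalize a header name: case-insensitive, dots and underscores ignored,
# so SNP.Id, SNP_ID and snpid all match.
normalize_header <- function(x) gsub("[._]", "", tolower(x))

# Read a delimited text table, sniffing comma / tab / whitespace from the
# header line.
read_sniffed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "qtlcoloc_io_error")
  }
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else if (grepl(",", header)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
}

# Map raw column names onto canonical names via a normalized lookup.
# `required` and `optional` are named character vectors canonical -> normalized
# header. Errors (schema class) name the first missing required column.
select_schema <- function(df, required, optional = character(), what = "table") {
  norm <- normalize_header(names(df))
  out <- list()
  for (canon in names(required)) {
    idx <- match(required[[canon]], norm)
    if (is.na(idx)) {
      abort(sprintf("%s is missing required column '%s'", what,
                    toupper(required[[canon]])),
            class = "qtlcoloc_schema_error")
    }
    out[[canon]] <- df[[idx]]
  }
  for (canon in names(optional)) {
    idx <- match(optional[[canon]], norm)
    if (!is.na(idx)) out[[canon]] <- df[[idx]]
  }
  as_tibble(out)
}

stopifnot_numeric <- function(x, col, what) {
  if (!is.numeric(x)) {
    abort(sprintf("%s column '%s' must be numeric", what, col),
          class = "qtlcoloc_schema_error")
  }
  invisible(x)
}
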