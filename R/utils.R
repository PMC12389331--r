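# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Strict TSV dialect used everywhere: UTF-8, tab separated, header row,
# no quoting, "." decimal separator.
#' @keywords internal
#' @noRd
read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8",
                          check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' @keywords internal
#' @noRd
write_tsv_strict <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8", eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

# Fixed 12-decimal formatting for score columns, so written files are
# byte-identical across runs and round-trip to 12 decimal digits.
#' @keywords internal
#' @noRd
format_score <- function(x) sprintf("%.12f", x)
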