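# Internal helpers shared across modules.

#' @keywords internal
db_stop <- function(msg, ..., class = "dreambench_validation_error") {
  stop(structure(
    class = c(class, "dreambench_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

db_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Falling factorial n * (n-1) * ... * (n-k+1)
#' @keywords internal
falling_factorial <- function(n, k) {
  stopifnot(k >= 0, n >= k)
  if (k == 0) return(1)
  prod(seq(n, n - k + 1))
}

#' Geometric mean of a positive vector
#' @keywords internal
geometric_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    db_stop("geometric mean requires finite positive values")
  }
  exp(mean(log(x)))
}

# Read a challenge TSV: tab-separated, '#' comments, UTF-8, no quoting.
read_tsv_raw <- function(path, header = TRUE, colClasses = NA) {
  if (!file.exists(path)) db_stop("file not found: %s", path)
  tryCatch(
    utils::read.table(path,
      sep = "\t", header = header, comment.char = "#",
      quote = "", stringsAsFactors = FALSE, check.names = FALSE,
      colClasses = colClasses, encoding = "UTF-8",
      na.strings = c("NA", "NaN", "")
    ),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame()
      } else {
        db_stop("cannot parse %s: %s", path, conditionMessage(e))
      }
    }
  )
}

write_tsv_raw <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = col.names, na = "NA"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}
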