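#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so that seeded helpers never perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a root seed
#'
#' Deterministically maps (root seed, stage label) to a 31-bit integer so that
#' every pipeline stage has its own reproducible random stream.
#'
#' @param seed Root integer seed.
#' @param label Character stage label.
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 69069 + h * 1013904223) %% 2147483647)
}

# log(sum(exp(x))) by rows of a matrix, -Inf-safe
row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx2 <- ifelse(is.finite(mx), mx, 0)
  mx2 + log(rowSums(exp(m - mx2)))
}

# lower median: for even n the smaller of the two central order statistics
median_lower <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[floor((n + 1) / 2)]
}

geomean <- function(x) exp(mean(log(x)))

#' Write a TSV with a '#'-prefixed header
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- read.table(path, sep = "\t", skip = 1L, header = FALSE,
                   col.names = cols, stringsAsFactors = FALSE,
                   comment.char = "")
  df
}
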