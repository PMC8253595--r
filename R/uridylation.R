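## Terminal-uridylation calling and frequency profiles.
##
## Read 2 starts at the RNA 3' terminus, so non-templated terminal uridines
## appear as leading 'A' calls preceding the poly(A) 'T' stretch.

#' Call terminal uridylation from read-2 base calls
#'
#' Counts the leading `A` bases of each read-2 call (the Us sitting 3' of
#' the poly(A) tail, read first); a tag is uridylated iff at least one is
#' present. Mono- vs oligo-uridylation is distinguishable from the count.
#'
#' @param read2 Character vector of read-2 base calls.
#' @return Integer vector of terminal-U counts.
#' @export
call_terminal_u <- function(read2) {
  nchar(sub("[^A].*$", "", read2))
}

#' Uridylation frequency by tail length
#'
#' Restricted to tags with tail length `>= min_tail` (2 nt by default),
#' reports the uridylated fraction per tail length. Tail-length strata with
#' no tags are absent from the output (missing, not 0).
#'
#' @param tags Tag table with `tail_length` and `terminal_U`.
#' @param min_tail Minimum tail length (nt).
#' @return Data frame `tail_length, n_tags, n_urid, fraction`.
#' @export
urid_frequency <- function(tags, min_tail = 2L) {
  stopifnot(all(c("tail_length", "terminal_U") %in% names(tags)))
  t2 <- tags[tags$tail_length >= min_tail, , drop = FALSE]
  if (!nrow(t2))
    return(data.frame(tail_length = integer(), n_tags = integer(),
                      n_urid = integer(), fraction = numeric()))
  sp <- split(t2$terminal_U, t2$tail_length)
  data.frame(tail_length = as.integer(names(sp)),
             n_tags = vapply(sp, length, 1L),
             n_urid = vapply(sp, sum, 1L),
             fraction = vapply(sp, mean, 1),
             row.names = NULL)
}

#' Positional U fraction near tail termini
#'
#' Fraction of `A` calls (terminal Us) at each of the first `k` read-2
#' positions, i.e. the `k` called bases nearest the RNA 3' terminus, among
#' tags with tail length `>= min_tail`.
#'
#' @param read2 Character vector of read-2 base calls.
#' @param tail_length Matching tail lengths.
#' @param k Number of terminal positions to profile.
#' @param min_tail Minimum tail length (nt).
#' @return Data frame `position` (1 = terminus-proximal), `u_fraction`.
#' @export
terminal_u_profile <- function(read2, tail_length, k = 2L, min_tail = 2L) {
  keep <- tail_length >= min_tail
  r <- read2[keep]
  data.frame(position = seq_len(k),
             u_fraction = vapply(seq_len(k), function(p)
               mean(substr(r, p, p) == "A"), numeric(1)))
}
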