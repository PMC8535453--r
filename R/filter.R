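# CDS quality filtering. Each rejected record is charged to exactly one
# rule, the first failing one in a fixed order, so the per-rule counts
# reconcile with the input size.

FILTER_RULES <- c("ambiguous_base", "too_short", "not_multiple_of_3",
                  "bad_start", "bad_stop", "internal_stop",
                  "not_longest_transcript")

#' Filter a CDS set
#'
#' Applies the standard CDS quality rules: the sequence must contain only
#' A/C/G/T, be at least `min_len` nucleotides (inclusive), have a length
#' divisible by three, start with ATG, end with TAA/TAG/TGA, contain no
#' in-frame stop codon before the terminal one, and be the longest
#' transcript of its gene (ties broken by lexicographically smallest id).
#' Each rejected record is charged to its first failing rule in the order
#' ambiguous_base, too_short, not_multiple_of_3, bad_start, bad_stop,
#' internal_stop, not_longest_transcript.
#'
#' @param x A [cds_set()].
#' @param min_len Minimum length in nucleotides (default 300, inclusive).
#' @return A list of class `cds_filter` with elements `cds` (the kept
#'   [cds_set()]) and `report` (class `filter_report`: `n_input`,
#'   `n_passed` and the named rejection counts).
#' @examples
#' fx <- generate_fixture()
#' f <- filter_cds(fx)
#' f$report
#' @export
filter_cds <- function(x, min_len = 300L) {
  stopifnot(inherits(x, "cds_set"))
  n <- length(x$id)
  fail <- rep(NA_character_, n)

  charge <- function(fail, cond, rule) {
    ifelse(is.na(fail) & cond, rule, fail)
  }

  seq <- x$seq
  len <- x$length
  fail <- charge(fail, grepl("[^ACGT]", seq), "ambiguous_base")
  fail <- charge(fail, len < min_len, "too_short")
  fail <- charge(fail, len %% 3L != 0L, "not_multiple_of_3")
  fail <- charge(fail, substring(seq, 1L, 3L) != "ATG", "bad_start")
  fail <- charge(fail, !substring(seq, len - 2L, len) %in% STOP_CODONS,
                 "bad_stop")

  # internal stops: only meaningful for records still in play (frame valid)
  cand <- which(is.na(fail))
  has_internal <- vapply(cand, function(i) {
    cod <- .split_codons(seq[i])
    any(cod[-length(cod)] %in% STOP_CODONS)
  }, logical(1L))
  fail[cand[has_internal]] <- "internal_stop"

  # longest primary transcript per gene among the survivors
  cand <- which(is.na(fail))
  if (length(cand)) {
    ord <- cand[order(-len[cand], x$id[cand])]
    keep_first <- ord[!duplicated(x$gene_id[ord])]
    losers <- setdiff(cand, keep_first)
    fail[losers] <- "not_longest_transcript"
  }

  kept <- which(is.na(fail))
  rejected <- table(factor(fail, levels = FILTER_RULES))
  report <- structure(
    list(n_input = n, n_passed = length(kept),
         n_rejected_by_rule = stats::setNames(as.integer(rejected),
                                              FILTER_RULES)),
    class = "filter_report"
  )
  structure(list(cds = .subset_cds(x, kept), report = report),
            class = "cds_filter")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("CDS filter report: %d input, %d passed\n",
              x$n_input, x$n_passed))
  nz <- x$n_rejected_by_rule[x$n_rejected_by_rule > 0L]
  if (length(nz)) {
    for (r in names(nz)) cat(sprintf("  %-24s %d\n", r, nz[[r]]))
  } else {
    cat("  no rejections\n")
  }
  invisible(x)
}

#' @export
print.cds_filter <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report A `filter_report` (from [filter_cds()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  df <- data.frame(
    rule = c("input", "passed", names(report$n_rejected_by_rule)),
    count = c(report$n_input, report$n_passed,
              unname(report$n_rejected_by_rule)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
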