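# ENC-GC3 and parity-rule-2 diagnostics. Under mutation pressure alone the
# observed ENC tracks the expected curve determined by GC3s, and third
# positions satisfy A = T and G = C (PR2).

#' Expected ENC under mutation pressure alone
#'
#' The expected effective number of codons of a gene whose codon usage is
#' fully determined by its GC3s value S:
#' `ENC = 2 + S + 29 / (S^2 + (1 - S)^2)`. The curve is symmetric about
#' S = 0.5 up to the linear term and attains its maximum 60.5 at S = 0.5.
#'
#' @param s GC3s value(s) in `[0, 1]`.
#' @return Numeric vector of expected ENC values.
#' @examples
#' enc_expected(c(0, 0.5, 1))
#' @export
enc_expected <- function(s) {
  stopifnot(all(s >= 0 & s <= 1, na.rm = TRUE))
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' ENC-GC3 plot table
#'
#' One point per gene: GC3s, observed ENC, expected ENC from
#' [enc_expected()], and the deviation observed minus expected. Genes whose
#' ENC is undefined are skipped and counted. The fraction of genes falling
#' below the expected curve is attached as an attribute (points well below
#' the curve indicate bias beyond mutation pressure).
#'
#' @param profiles A [gene_profiles()] data frame.
#' @return Data frame of class `enc_gc3` with columns `id`, `gc3s`,
#'   `enc_obs`, `enc_exp`, `deviation`, plus attributes `frac_below` and
#'   `n_skipped`.
#' @export
enc_gc3_table <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  ok <- !is.na(profiles$enc) & !is.na(profiles$gc3s)
  d <- profiles[ok, , drop = FALSE]
  out <- data.frame(
    id = d$id, gc3s = d$gc3s, enc_obs = d$enc,
    enc_exp = enc_expected(d$gc3s),
    stringsAsFactors = FALSE
  )
  out$deviation <- out$enc_obs - out$enc_exp
  rownames(out) <- NULL
  attr(out, "frac_below") <- if (nrow(out)) mean(out$deviation < 0) else NA_real_
  attr(out, "n_skipped") <- sum(!ok)
  class(out) <- c("enc_gc3", "data.frame")
  out
}

#' @export
plot.enc_gc3 <- function(x, ...) {
  graphics::plot(x$gc3s, x$enc_obs, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "GC3s", ylab = "ENC", xlim = c(0, 1),
                 ylim = c(20, 62), ...)
  s <- seq(0.01, 0.99, by = 0.01)
  graphics::lines(s, enc_expected(s), lwd = 2)
  invisible(x)
}

#' Parity rule 2 coordinates
#'
#' Per-gene PR2 coordinates `x = G3s / (G3s + C3s)` and
#' `y = A3s / (A3s + T3s)`, plus the genome-level GC-bias (mean of x) and
#' AT-bias (mean of y), unweighted over genes. Under strict parity both
#' coordinates are 0.5. Genes with a zero denominator are excluded from the
#' corresponding mean and counted.
#'
#' @param profiles A [gene_profiles()] data frame.
#' @return List of class `pr2`: `points` (data frame `id`, `x`, `y`),
#'   `mean_gc_bias`, `mean_at_bias`, `n_excluded_x`, `n_excluded_y`.
#' @export
pr2_coordinates <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  gx <- profiles$g3s + profiles$c3s
  ax <- profiles$a3s + profiles$t3s
  x <- ifelse(!is.na(gx) & gx > 0, profiles$g3s / gx, NA_real_)
  y <- ifelse(!is.na(ax) & ax > 0, profiles$a3s / ax, NA_real_)
  pts <- data.frame(id = profiles$id, x = x, y = y,
                    stringsAsFactors = FALSE)
  structure(
    list(points = pts,
         mean_gc_bias = mean(x, na.rm = TRUE),
         mean_at_bias = mean(y, na.rm = TRUE),
         n_excluded_x = sum(is.na(x)),
         n_excluded_y = sum(is.na(y))),
    class = "pr2"
  )
}

#' @export
print.pr2 <- function(x, ...) {
  cat(sprintf(
    "PR2: %d genes; GC-bias (mean G3s/(G3s+C3s)) = %.3f; AT-bias (mean A3s/(A3s+T3s)) = %.3f\n",
    nrow(x$points), x$mean_gc_bias, x$mean_at_bias))
  invisible(x)
}

#' @export
plot.pr2 <- function(x, ...) {
  graphics::plot(x$points$x, x$points$y, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("darkorange", 0.5),
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "G3s / (G3s + C3s)", ylab = "A3s / (A3s + T3s)",
                 ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2)
  invisible(x)
}
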