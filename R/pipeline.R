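# End-to-end orchestration: filter -> per-gene metrics -> ENC-GC3 / PR2 ->
# correspondence analysis -> optimal codons -> positional hydrogen bonds ->
# skew trends, with every stage's table written as TSV and a
# machine-readable JSON summary.

# fixed 6-decimal formatting so TSV diffs are stable
.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full codon-usage analysis pipeline
#'
#' Executes every stage on one CDS collection and writes all tables plus a
#' JSON summary to `out_dir`: CDS filtering, per-gene profiles, codon
#' count and RSCU matrices, ENC-GC3 and PR2 tables, correspondence
#' analysis (gene/codon coordinates, inertia, GC bands, axis
#' correlations), optimal codons from the axis-1 extremes, the positional
#' hydrogen-bond profile and the aggregate skew profile. All randomness
#' (synthetic generation, bootstraps) derives from `seed`.
#'
#' @param input A FASTA path, a [cds_set()], or a
#'   [synthetic_genome_spec()] (generated with seed `seed`).
#' @param out_dir Output directory (created if missing).
#' @param min_len,k_axes,fraction,alpha,max_pos,n_boot,min_coverage,window,step,max_len,run_length
#'   Stage parameters, passed through to the stage functions.
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @param make_plots Also write PDF plots of the main figures
#'   (default FALSE).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(input, out_dir,
                         min_len = 300L, k_axes = 4L, fraction = 0.05,
                         alpha = 0.01, max_pos = 500L, n_boot = 1000L,
                         min_coverage = 30L, window = 100L, step = 1L,
                         max_len = 1000L, run_length = 10L,
                         seed = 1L, make_plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  x <- .stage("input", {
    if (inherits(input, "cds_set")) {
      input
    } else if (inherits(input, "synthetic_genome_spec")) {
      input$seed <- seed
      generate_genome(input)
    } else if (is.character(input) && length(input) == 1L) {
      read_cds_fasta(input)
    } else {
      stop("unsupported input type")
    }
  })

  f <- .stage("filter", filter_cds(x, min_len = min_len))
  write_filter_report(f$report, file.path(out_dir, "filter_report.tsv"))
  write_cds_fasta(f$cds, file.path(out_dir, "filtered.fasta"))

  prof <- .stage("metrics", gene_profiles(f$cds))
  .write_tsv(prof, file.path(out_dir, "gene_profiles.tsv"))
  counts <- attr(prof, "counts")
  utils::write.table(data.frame(id = rownames(counts), counts,
                                check.names = FALSE),
                     file.path(out_dir, "codon_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  eg <- .stage("encgc3", enc_gc3_table(prof))
  .write_tsv(eg, file.path(out_dir, "enc_gc3.tsv"))

  pr2 <- .stage("pr2", pr2_coordinates(prof))
  .write_tsv(pr2$points, file.path(out_dir, "pr2.tsv"))

  rm_ <- .stage("coa", build_rscu_matrix(prof))
  .write_tsv(data.frame(id = rownames(rm_), as.data.frame(unclass(rm_)),
                        check.names = FALSE),
             file.path(out_dir, "rscu_matrix.tsv"))
  coa <- .stage("coa", run_coa(rm_, k = k_axes))
  .write_tsv(data.frame(id = rownames(coa$row_coords), coa$row_coords,
                        check.names = FALSE),
             file.path(out_dir, "coa_gene_coords.tsv"))
  .write_tsv(data.frame(codon = rownames(coa$col_coords), coa$col_coords,
                        check.names = FALSE),
             file.path(out_dir, "coa_codon_coords.tsv"))
  .write_tsv(data.frame(axis = seq_along(coa$inertia_fraction),
                        inertia_fraction = coa$inertia_fraction),
             file.path(out_dir, "coa_inertia.tsv"))
  bands <- classify_gc_bands(prof)
  .write_tsv(data.frame(id = prof$id, gc = prof$gc,
                        band = as.character(bands)),
             file.path(out_dir, "gc_bands.tsv"))
  corr <- .stage("coa", axis_correlations(coa, prof))
  .write_tsv(corr, file.path(out_dir, "axis_correlations.tsv"))

  opt <- .stage("optimal", {
    b <- select_extreme_genes(coa, counts, fraction = fraction)
    call_optimal_codons(b, alpha = alpha)
  })
  .write_tsv(opt, file.path(out_dir, "optimal_codons.tsv"))

  pos <- .stage("positional",
                positional_profile(f$cds, max_pos = max_pos,
                                   n_boot = n_boot,
                                   min_coverage = min_coverage,
                                   seed = seed + 1L))
  .write_tsv(pos, file.path(out_dir, "positional_profile.tsv"))
  crossing <- crossing_position(pos, run_length = run_length)

  sk <- .stage("skew",
               aggregate_skew_profile(f$cds, max_len = max_len,
                                      window = window, step = step,
                                      min_coverage = min_coverage,
                                      seed = seed + 2L))
  .write_tsv(sk$profile, file.path(out_dir, "skew_profile.tsv"))

  if (make_plots) {
    plot_one <- function(file, expr) {
      grDevices::pdf(file.path(out_dir, file), width = 6, height = 5)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr
    }
    plot_one("enc_gc3.pdf", plot(eg))
    plot_one("pr2.pdf", plot(pr2))
    plot_one("coa.pdf", plot(coa, bands = bands))
    plot_one("positional.pdf", plot(pos))
    plot_one("skew.pdf", plot(sk))
  }

  summary <- list(
    params = list(min_len = min_len, k_axes = k_axes, fraction = fraction,
                  alpha = alpha, max_pos = max_pos, n_boot = n_boot,
                  min_coverage = min_coverage, window = window,
                  step = step, max_len = max_len,
                  run_length = run_length, seed = seed),
    filter = list(n_input = f$report$n_input,
                  n_passed = f$report$n_passed,
                  rejected = as.list(f$report$n_rejected_by_rule)),
    metrics = list(
      n_genes = nrow(prof),
      mean_gc = mean(prof$gc), mean_gc3s = mean(prof$gc3s, na.rm = TRUE),
      mean_enc = mean(prof$enc, na.rm = TRUE),
      mean_l_aa = mean(prof$l_aa), mean_gravy = mean(prof$gravy),
      mean_aromo = mean(prof$aromo)
    ),
    enc_gc3 = list(frac_below_curve = attr(eg, "frac_below"),
                   n_skipped = attr(eg, "n_skipped")),
    pr2 = list(mean_gc_bias = pr2$mean_gc_bias,
               mean_at_bias = pr2$mean_at_bias),
    coa = list(inertia_fraction = coa$inertia_fraction,
               axis1_r2 = stats::setNames(as.list(corr$r2), corr$index)),
    optimal = list(n_optimal = sum(opt$optimal),
                   codons = sort(opt$codon[opt$optimal])),
    positional = list(n_positions = nrow(pos),
                      crossing_position = crossing,
                      first_mean_hbonds = pos$mean_hbonds[1L],
                      last_mean_hbonds = pos$mean_hbonds[nrow(pos)]),
    skew = list(slope_cg = sk$slope_cg, slope_at = sk$slope_at)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
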