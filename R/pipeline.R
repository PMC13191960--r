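#' Run the full synthetic analysis pipeline
#'
#' Generates a self-contained synthetic study (Hi-C matrix with embedded
#' ecDNA/BFB events, a chromothriptic chromosome, a convergent multi-sample
#' cohort, an expression cohort, and a clonal mutation matrix), then runs
#' every analysis stage: Hi-C evidence testing, chromothripsis calling,
#' gene/event copy-number annotation, cross-sample similarity,
#' regulatory-peak enrichment, the nested expression scan, and the
#' neighbor-joining phylogeny. All inputs and per-stage results are written
#' as TSV/Newick files under `out_dir`; reruns with the same seed are
#' byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param n_perm permutations for the enrichment stage.
#' @param validation a `validation_config`.
#' @param chromo a `chromothripsis_config`.
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_all <- function(out_dir, seed = 1, n_perm = 200,
                    validation = validation_config(),
                    chromo = chromothripsis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  log_lines <- c(paste("complexSV run_all, package version",
                       as.character(utils::packageVersion("complexSV"))),
                 paste("seed:", seed))

  ## stage 1: Hi-C evidence on a simulated two-event scenario
  genome <- c(chrA = 3e6, chrB = 2e6)
  ev_cis <- amplicon_event("demo_ecDNA_cis", "demo", "ecDNA",
                           data.frame(chrom = "chrA", start = 1.0e6,
                                      end = 1.2e6, copy_number = 20),
                           amp_factor = 10)
  ev_trans <- amplicon_event("demo_ecDNA_trans", "demo", "ecDNA",
                             data.frame(chrom = c("chrA", "chrB"),
                                        start = c(2.2e6, 0.9e6),
                                        end = c(2.35e6, 1.05e6),
                                        copy_number = 18),
                             amp_factor = 10)
  sc <- sim_scenario(genome, list(ev_cis, ev_trans), purity = 0.7,
                     seed = seed)
  cm <- simulate_hic(sc)
  write_contact_matrix(cm, p("hic_bins.tsv"), p("hic_pixels.tsv"))
  write_events(list(ev_cis, ev_trans), p("events.tsv"))
  evid <- validate_events(list(ev_cis, ev_trans), cm, validation)
  ev_tab <- do.call(rbind, lapply(evid, function(e) {
    data.frame(event_id = e$event_id, class = e$class,
               category = e$category, supported = e$supported,
               support_reason = e$support_reason, stringsAsFactors = FALSE)
  }))
  utils::write.table(ev_tab, p("hic_evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seg_tab <- do.call(rbind, lapply(evid, function(e) {
    cbind(event_id = e$event_id, e$segment_results)
  }))
  utils::write.table(seg_tab, p("hic_evidence_segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage 2: chromothripsis on a simulated shattered chromosome
  ct <- simulate_chromothripsis("chrC", c(2e6, 4.5e6), n_inv = 20,
                                n_del = 12, n_switch = 20,
                                chrom_length = 6e6, seed = seed)
  write_breakpoints(ct$breakpoints, p("chromothripsis_sv.bedpe"))
  write_copy_segments(ct$segments, p("chromothripsis_cn.tsv"))
  wins <- count_window_features(ct$breakpoints, ct$segments, "chrC", chromo)
  ct_call <- call_chromothripsis(wins)
  utils::write.table(wins[wins$called, ], p("chromothripsis_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: gene CN annotation on the chromothriptic sample
  genes <- data.frame(gene_id = c("geneA", "geneB"),
                      chrom = "chrC", start = c(2.1e6, 5.0e6),
                      end = c(2.2e6, 5.1e6), stringsAsFactors = FALSE)
  gene_cn <- annotate_gene_cn(ct$segments, genes)
  utils::write.table(gene_cn, p("gene_cn.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage 4: cross-sample convergence
  cohort <- simulate_cohort(4, list(chrom = "chrX", start = 6.6e7,
                                    end = 6.72e7),
                            shared_pairs = list(c(1, 2)), seed = seed)
  sim <- convergence_classify(lapply(cohort, `[[`, "events"))
  utils::write.table(sim, p("similarity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage 5: enrichment of the cohort's events in a peak set
  queries <- do.call(rbind, lapply(cohort, function(s) {
    s$events[[1]]$segments[, c("chrom", "start", "end")]
  }))
  rownames(queries) <- NULL
  peaks <- data.frame(chrom = "chrX",
                      start = seq(6.55e7, 6.8e7, by = 5e5),
                      end = seq(6.55e7, 6.8e7, by = 5e5) + 2e4)
  enr <- permutation_overlap_test(queries, peaks, c(chrX = 1.56e8),
                                  n_perm = n_perm, seed = seed)
  utils::write.table(
    data.frame(observed = enr$observed_overlap_count,
               empirical_p = enr$empirical_p, n_perm = enr$n_perm),
    p("enrichment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 6: expression scan (one true ecDNA gene among nulls)
  records <- c(list(AR = simulate_expression(60, beta_ecdna = 1,
                                             seed = seed)),
               lapply(seq_len(9), function(k) {
                 simulate_expression(60, beta_ecdna = 0, seed = seed + k)
               }))
  names(records)[-1] <- paste0("null", seq_len(9))
  scan <- ecdna_expression_scan(records)
  utils::write.table(scan, p("expression_scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage 7: phylogeny from a simulated clonal mutation matrix
  true_tree <- ape::read.tree(text = "((S1:1,S2:1):1,(S3:1,S4:1):1);")
  mut <- simulate_mutations(true_tree, mutations_per_branch = 5,
                            seed = seed)
  write_mutation_matrix(mut$matrix, p("mutations.tsv"))
  tree <- mutation_phylogeny(mut$matrix, newick_path = p("tree.nwk"))

  ## merged per-event summary
  summary_tab <- data.frame(
    event_id = ev_tab$event_id, class = ev_tab$class,
    category = ev_tab$category,
    truth = "simulated cSV", hic_supported = ev_tab$supported,
    event_weighted_cn = vapply(list(ev_cis, ev_trans), event_weighted_cn,
                               numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.table(summary_tab, p("event_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_lines <- c(log_lines,
                 paste("config hash:",
                       sum(utils::object.size(validation),
                           utils::object.size(chromo))),
                 paste("events supported:", sum(ev_tab$supported)),
                 paste("chromothripsis positive:",
                       any(ct_call$positive)))
  writeLines(log_lines, p("run_log.txt"))

  invisible(list(hic_evidence = evid, chromothripsis = ct_call,
                 windows = wins, gene_cn = gene_cn, similarity = sim,
                 enrichment = enr, expression_scan = scan, tree = tree,
                 summary = summary_tab))
}
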