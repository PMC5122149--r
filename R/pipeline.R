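#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end analysis in one list. The
#' defaults are the package's standard settings: bootstrap with 100
#' replicates, support threshold 60, G+C windows of 1000 bp at a step of
#' 30 bp, composition z threshold 2.0, neighbourhood Jaccard threshold 0.3,
#' long-branch multiplier 4. Stages can be toggled individually; with
#' `simulate = TRUE` the inputs come from [simulate_chs_family()] under
#' `sim`, otherwise from the `input_*` paths.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param simulate Generate inputs with the bundled simulator.
#' @param sim A [fixture_config()] used when `simulate = TRUE`.
#' @param stages Named logical vector toggling `scan`, `trim`, `tree`,
#'   `classify`, `hgt`, `recomb`.
#' @param support_min Bootstrap support threshold.
#' @param bootstrap_reps Bootstrap replicates per tree.
#' @param corrections Two distance corrections (the two inference
#'   settings).
#' @param window,step G+C window parameters (bp).
#' @param z_min Composition z threshold.
#' @param jaccard_min Neighbourhood-similarity threshold.
#' @param k_long_branch Long-branch multiplier.
#' @param min_gap Catalytic-motif D separation.
#' @param trim_score_cutoff,trim_gap_cutoff,trim_window Trimming
#'   parameters.
#' @param pssm_pseudocount,pssm_fpr,pssm_shuffles PSSM screen parameters.
#' @param input_proteins,input_alignment,input_cds,input_taxon_map,input_neighborhoods,input_contexts,input_class_proposals
#'   Input paths used when `simulate = FALSE`.
#' @return A list of class `chs_pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("chsevol_run_"), seed = 1,
                            simulate = TRUE, sim = fixture_config(),
                            stages = c(scan = TRUE, trim = TRUE,
                                       tree = TRUE, classify = TRUE,
                                       hgt = TRUE, recomb = TRUE),
                            support_min = 60, bootstrap_reps = 100,
                            corrections = c("p", "poisson"),
                            window = 1000, step = 30, z_min = 2,
                            jaccard_min = 0.3, k_long_branch = 4,
                            min_gap = 10,
                            trim_score_cutoff = 0.5, trim_gap_cutoff = 0.5,
                            trim_window = 3,
                            pssm_pseudocount = 1, pssm_fpr = 0.01,
                            pssm_shuffles = 200,
                            input_proteins = NULL, input_alignment = NULL,
                            input_cds = NULL, input_taxon_map = NULL,
                            input_neighborhoods = NULL,
                            input_contexts = NULL,
                            input_class_proposals = NULL) {
  cfg <- as.list(environment())
  defaults <- eval(formals(pipeline_config)$stages)
  missing_stages <- setdiff(names(defaults), names(cfg$stages))
  cfg$stages <- c(cfg$stages, defaults[missing_stages])
  assert_that(support_min >= 0 && support_min <= 101 &&
                bootstrap_reps >= 1 && window >= 1 && step >= 1 &&
                z_min >= 0 && jaccard_min >= 0 && jaccard_min <= 1 &&
                k_long_branch > 0,
              "a threshold is outside its documented range",
              class = "chsevol_config_error")
  assert_that(length(corrections) == 2,
              "exactly two distance corrections are required",
              class = "chsevol_config_error")
  structure(cfg, class = "chs_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error, and omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return A `chs_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0,
              paste0("unknown config keys: ", paste(bad, collapse = ", ")),
              class = "chsevol_config_error")
  if (!is.null(raw$sim)) raw$sim <- do.call(fixture_config, raw$sim)
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> motif/PSSM scan -> trim -> trees (two
#' distance settings, bootstrap, outgroup rooting, long-branch flags) ->
#' class definition -> horizontal-transfer evidence -> chimera scan, writing
#' every intermediate artifact under `config$out_dir` and returning a run
#' report whose stage counts reconcile. All randomness derives from
#' `config$seed`, so two runs with the same config produce byte-identical
#' output files.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `chs_run_report`: list with `report` (tibble:
#'   `stage`, `n_in`, `n_out`, `n_discarded`, `note`), `config`, `outputs`
#'   (named paths), `wall_time_s`, and the main result objects
#'   (`classes`, `hgt_calls`, `chimera_reports`, `boot_trees`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  assert_that(inherits(config, "chs_pipeline_config"),
              "config must come from pipeline_config()",
              class = "chsevol_config_error")
  t0 <- Sys.time()
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  report <- list()
  note_row <- function(stage, n_in, n_out, n_discarded = 0L, note = "") {
    report[[length(report) + 1L]] <<- tibble(
      stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
      n_discarded = as.integer(n_discarded), note = note)
  }

  # ---- inputs ---------------------------------------------------------
  sim <- NULL
  if (isTRUE(config$simulate)) {
    fix <- emit_fixture(config$sim, config$seed,
                        file.path(out_dir, "fixture"))
    sim <- fix$simulation
    paths <- c(paths, fix$files)
    genes <- sim$genes
    aln <- sim$alignment
    taxon_groups <- sim$taxon_groups
    neighborhoods <- sim$neighborhoods
    contexts <- sim$contexts
    note_row("simulate", 0L, nrow(genes),
             note = paste0("planted hgt=", sum(genes$is_hgt),
                           " decayed=", sum(genes$motif_decayed)))
  } else {
    assert_that(!is.null(config$input_proteins) &&
                  !is.null(config$input_alignment) &&
                  !is.null(config$input_taxon_map),
                "missing input for a non-simulated run: need proteins, alignment, taxon_map",
                class = "chsevol_config_error")
    prot <- read_fasta(config$input_proteins)
    tmap <- read_taxon_map(config$input_taxon_map)
    genes <- tibble(gene_id = names(prot), protein = unname(prot)) |>
      left_join(tmap, by = c(gene_id = "seq_id")) |>
      mutate(cds = NA_character_, is_hgt = NA, motif_decayed = NA)
    if (!is.null(config$input_cds)) {
      cds <- read_fasta(config$input_cds)
      genes$cds <- unname(cds[genes$gene_id])
    }
    aln <- read_alignment(config$input_alignment)
    taxon_groups <- setNames(tmap$group, tmap$taxon)
    taxon_groups <- taxon_groups[!duplicated(names(taxon_groups))]
    neighborhoods <- if (!is.null(config$input_neighborhoods)) {
      read_neighborhood(config$input_neighborhoods)
    } else NULL
    contexts <- if (!is.null(config$input_contexts)) {
      read_fasta(config$input_contexts)
    } else NULL
    note_row("load", 0L, nrow(genes), note = "inputs from files")
  }

  # ---- scan: catalytic motifs + PSSM screen ---------------------------
  kept <- genes
  if (isTRUE(config$stages[["scan"]])) {
    parts <- filter_candidates(genes, min_gap = config$min_gap)
    kept <- parts$kept
    pssm_note <- ""
    if (nrow(kept) >= 2) {
      rows <- aln[intersect(rownames(aln), kept$gene_id), , drop = FALSE]
      seed_rows <- rows[, select_pssm_block(rows), drop = FALSE]
      pssm <- build_pssm(seed_rows, pseudocount = config$pssm_pseudocount)
      pssm <- calibrate_pssm_threshold(
        pssm, gsub("-", "", aln_to_strings(seed_rows), fixed = TRUE),
        n_shuffles = config$pssm_shuffles, fpr = config$pssm_fpr,
        seed = derive_seed(config$seed, 21))
      hits <- vapply(kept$protein, function(p)
        nrow(pssm_scan(pssm, p)), integer(1), USE.NAMES = FALSE)
      pssm_note <- paste0("pssm hits>=1 for ", sum(hits >= 1), "/",
                          nrow(kept))
      paths <- c(paths, pssm = write_pssm(pssm, file.path(out_dir, "screen.pssm")))
    }
    dub_path <- file.path(out_dir, "dubious.tsv")
    write_tsv_plain(parts$dubious["gene_id"], dub_path)
    paths <- c(paths, dubious = dub_path)
    note_row("scan", nrow(genes), nrow(kept), nrow(parts$dubious),
             note = pssm_note)
  }

  aln_kept <- aln[intersect(rownames(aln), kept$gene_id), , drop = FALSE]

  # ---- trim -----------------------------------------------------------
  trimmed <- aln_kept
  if (isTRUE(config$stages[["trim"]])) {
    trimmed <- trim_alignment(aln_kept,
                              score_cutoff = config$trim_score_cutoff,
                              gap_cutoff = config$trim_gap_cutoff,
                              smoothing_window = config$trim_window)
    trim_path <- file.path(out_dir, "trimmed_alignment.fasta")
    write_alignment(trimmed, trim_path)
    map_path <- file.path(out_dir, "trim_index_map.tsv")
    write_index_map(trimmed, map_path)
    paths <- c(paths, trimmed = trim_path, trim_map = map_path)
    note_row("trim", ncol(aln_kept), ncol(trimmed),
             ncol(aln_kept) - ncol(trimmed), note = "columns")
  }

  # ---- trees ----------------------------------------------------------
  boot_trees <- list()
  rooted_trees <- list()
  long_branches <- character(0)
  outgroup_ids <- grep("^out\\|", rownames(trimmed), value = TRUE)
  if (isTRUE(config$stages[["tree"]])) {
    for (k in seq_along(config$corrections)) {
      corr <- config$corrections[[k]]
      bt <- bootstrap_support(trimmed, n_reps = config$bootstrap_reps,
                              correction = corr,
                              seed = derive_seed(config$seed, 30 + k))
      boot_trees[[corr]] <- bt
      tr <- bt$tree
      if (length(outgroup_ids)) {
        tr <- tryCatch(root_by_outgroup(tr, outgroup_ids),
                       chsevol_error = function(e) tr)
      }
      rooted_trees[[corr]] <- tr
      tree_path <- file.path(out_dir, paste0("nj_", corr, ".nwk"))
      write_newick(tr, tree_path)
      paths <- c(paths, setNames(tree_path, paste0("tree_", corr)))
      note_row(paste0("tree_", corr), nrow(trimmed), length(tr$tip.label),
               bt$n_discarded,
               note = paste0("bootstrap reps=", bt$n_reps,
                             " valid=", bt$n_valid))
    }
    long_branches <- flag_long_branches(rooted_trees[[1]],
                                        k = config$k_long_branch)
    lb_path <- file.path(out_dir, "long_branches.tsv")
    write_tsv_plain(tibble(gene_id = long_branches), lb_path)
    paths <- c(paths, long_branches = lb_path)
  }

  # ---- classify -------------------------------------------------------
  classes <- NULL
  if (isTRUE(config$stages[["classify"]]) && length(rooted_trees) == 2) {
    proposals <- pipeline_class_proposals(config, sim, kept, outgroup_ids)
    if (length(proposals)) {
      classes <- define_classes(rooted_trees[[1]], rooted_trees[[2]],
                                proposals, support_min = config$support_min)
      cls_path <- file.path(out_dir, "classes.tsv")
      write_tsv_plain(select(as_tibble(classes), -"members"), cls_path)
      paths <- c(paths, classes = cls_path)
      note_row("classify", length(proposals), sum(classes$accepted),
               sum(!classes$accepted), note = "proposals accepted/rejected")
    }
  }

  # ---- hgt ------------------------------------------------------------
  hgt_calls <- NULL
  if (isTRUE(config$stages[["hgt"]]) && length(rooted_trees)) {
    hgt_calls <- pipeline_hgt_stage(config, rooted_trees[[length(rooted_trees)]],
                                    kept, taxon_groups, neighborhoods,
                                    contexts, outgroup_ids)
    hgt_path <- file.path(out_dir, "hgt_calls.tsv")
    write_tsv_plain(as_tibble(hgt_calls), hgt_path)
    paths <- c(paths, hgt_calls = hgt_path)
    note_row("hgt", nrow(kept) - length(outgroup_ids), nrow(hgt_calls),
             note = paste0("strong=", sum(hgt_calls$verdict == "strong"),
                           " weak=", sum(hgt_calls$verdict == "weak")))
  }

  # ---- recomb ---------------------------------------------------------
  chimera_reports <- NULL
  if (isTRUE(config$stages[["recomb"]])) {
    chimera_reports <- pipeline_recomb_stage(config, aln_kept, kept,
                                             classes, outgroup_ids)
    rec_path <- file.path(out_dir, "chimera_reports.tsv")
    write_tsv_plain(chimera_reports, rec_path)
    paths <- c(paths, chimera = rec_path)
    note_row("recomb", nrow(kept), nrow(chimera_reports),
             note = paste0("chimeric=", sum(chimera_reports$chimeric)))
  }

  report_tb <- bind_rows(report)
  rep_path <- file.path(out_dir, "run_report.tsv")
  write_tsv_plain(report_tb, rep_path)
  paths <- c(paths, report = rep_path)

  out <- structure(list(report = report_tb, config = config,
                        outputs = paths,
                        wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs")),
                        classes = classes, hgt_calls = hgt_calls,
                        chimera_reports = chimera_reports,
                        boot_trees = boot_trees),
                   class = "chs_run_report")
  validate_run_report(out)
  out
}

# Contiguous gapless block of alignment columns for the PSSM screen, the
# most conserved such window (domain profiles are short and local: a
# gapless block guarantees each family member carries the block as one
# contiguous segment, so a sliding-window scan can find it).
select_pssm_block <- function(aln, width = 40) {
  gapless <- colSums(aln == GAP_CHAR) == 0
  if (ncol(aln) <= width) return(seq_len(ncol(aln)))
  score <- score_columns(aln, method = "entropy") * gapless
  run_ok <- vapply(seq_len(ncol(aln) - width + 1), function(s)
    all(gapless[s:(s + width - 1)]), logical(1))
  win <- vapply(seq_len(ncol(aln) - width + 1), function(s)
    sum(score[s:(s + width - 1)]), numeric(1))
  if (any(run_ok)) {
    s <- which(run_ok)[which.max(win[run_ok])]
  } else {
    s <- which.max(win) # heavily gapped alignment: best-effort window
  }
  s:(s + width - 1)
}

# Ground-truth-free class proposals: user file when given; in simulate mode
# the true divisions (donor group plus its transferred descendants, versus
# the recipient group's vertically inherited genes).
pipeline_class_proposals <- function(config, sim, kept, outgroup_ids) {
  if (!is.null(config$input_class_proposals)) {
    tb <- readr::read_tsv(config$input_class_proposals,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    keep <- tb$seq_id %in% kept$gene_id
    return(split(tb$seq_id[keep], tb$class[keep]))
  }
  if (is.null(sim)) return(list())
  g <- kept |> filter(!.data$gene_id %in% outgroup_ids)
  donor <- sim$config$hgt_donor_group
  props <- list()
  for (grp in unique(g$group)) {
    members <- if (grp == donor) {
      g$gene_id[g$group == grp | g$is_hgt]
    } else {
      g$gene_id[g$group == grp & !g$is_hgt]
    }
    if (length(members) >= 2) props[[paste0("division_", grp)]] <- members
  }
  props
}

pipeline_hgt_stage <- function(config, tree, kept, taxon_groups,
                               neighborhoods, contexts, outgroup_ids) {
  focal <- setdiff(kept$gene_id, outgroup_ids)
  sub_groups <- taxon_groups[names(taxon_groups) != "out"]
  keep_tips <- setdiff(tree$tip.label, outgroup_ids)
  inc <- detect_incongruent_leaves(
    if (length(outgroup_ids)) ape::drop.tip(tree, outgroup_ids) else tree,
    sub_groups, support_min = config$support_min)
  gc_flags <- setNames(rep(FALSE, length(focal)), focal)
  gc_z <- setNames(rep(NA_real_, length(focal)), focal)
  if (!is.null(contexts)) {
    for (gid in intersect(focal, names(contexts))) {
      cds <- kept$cds[kept$gene_id == gid][1]
      if (is.na(cds)) next
      prof <- gc_windows(contexts[[gid]], window = config$window,
                         step = config$step)
      if (nrow(prof) == 0) next
      an <- gc_anomaly(cds, prof, z_min = config$z_min)
      gc_flags[gid] <- an$flag
      gc_z[gid] <- an$z
    }
  }
  syn_ids <- character(0)
  if (!is.null(neighborhoods) && nrow(neighborhoods)) {
    genome_groups <- taxon_groups
    comps <- detect_cotransfer(neighborhoods, genome_groups,
                               focal_gene_ids = focal,
                               jaccard_min = config$jaccard_min)
    syn_ids <- unique(unlist(comps$gene_ids))
  }
  combine_evidence(tibble(
    seq_id = focal,
    incongruent = focal %in% inc$leaf,
    gc_flag = unname(gc_flags[focal]),
    gc_z = unname(gc_z[focal]),
    synteny = focal %in% syn_ids))
}

pipeline_recomb_stage <- function(config, aln_kept, kept, classes,
                                  outgroup_ids) {
  motif <- motif_definition("QXXXY", "QXXXY")
  empty <- tibble(seq_id = character(), breakpoint = integer(),
                  n_group = character(), c_group = character(),
                  n_support = double(), c_support = double(),
                  chimeric = logical(), note = character())
  candidates <- kept$gene_id[vapply(kept$protein, function(p)
    length(detect_motif_duplication(p, motif)) >= 2, logical(1),
    USE.NAMES = FALSE)]
  candidates <- setdiff(candidates, outgroup_ids)
  if (!length(candidates) || is.null(classes) ||
      sum(classes$accepted) < 2) {
    return(empty)
  }
  membership <- class_membership(classes)
  rows <- list()
  for (gid in candidates) {
    refs <- membership[setdiff(names(membership), gid)]
    brow <- paste(aln_kept[gid, ], collapse = "")
    bp <- locate_breakpoint(brow, motif)
    if (is.null(bp)) next
    rep_ <- tryCatch(
      detect_chimera(aln_kept, gid, refs, bp,
                     support_min = config$support_min,
                     n_reps = config$bootstrap_reps,
                     correction = config$corrections[[2]],
                     seed = derive_seed(config$seed, 70 + length(rows))),
      chsevol_error = function(e) NULL)
    if (!is.null(rep_)) rows[[gid]] <- rep_
  }
  if (length(rows)) bind_rows(rows) else empty
}

#' Check internal consistency of a run report
#'
#' Verifies that stage counts reconcile: each stage's input count equals the
#' previous producing stage's output, and kept + discarded equals input for
#' the filtering stages.
#'
#' @param x A `chs_run_report`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_run_report <- function(x) {
  rb <- x$report
  if ("scan" %in% rb$stage) {
    src <- rb[rb$stage %in% c("simulate", "load"), ]
    scan <- rb[rb$stage == "scan", ]
    assert_that(scan$n_in == src$n_out,
                "scan input does not match generated genes")
    assert_that(scan$n_in == scan$n_out + scan$n_discarded,
                "scan kept + dubious != input")
  }
  invisible(TRUE)
}

#' @export
print.chs_run_report <- function(x, ...) {
  cat("chsevol pipeline run (", format(x$wall_time_s, digits = 3),
      " s)\n", sep = "")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' @export
glance.chs_run_report <- function(x, ...) {
  tibble(n_stages = nrow(x$report),
         n_genes = x$report$n_out[x$report$stage %in% c("simulate", "load")][1],
         n_classes_accepted = if (is.null(x$classes)) NA_integer_
                              else sum(x$classes$accepted),
         n_strong_hgt = if (is.null(x$hgt_calls)) NA_integer_
                        else sum(x$hgt_calls$verdict == "strong"),
         n_chimeric = if (is.null(x$chimera_reports)) NA_integer_
                      else sum(x$chimera_reports$chimeric),
         wall_time_s = x$wall_time_s)
}
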