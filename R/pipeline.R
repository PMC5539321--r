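#' End-to-end pipeline orchestration
#'
#' A single-command driver running the stages in dependency order:
#' io -> homology -> pangenome -> classify -> codon -> phylo ->
#' selection -> hostrange -> growth. Each stage writes its tabular
#' outputs under the configured output directory and contributes to a
#' machine-readable `summary.json`; given the same configuration and
#' seed the summary is byte-identical across runs.
#'
#' @name cli_pipeline
NULL

pv_config_keys <- c(
  "fasta", "annotation", "cohort", "host_range", "isolates", "growth",
  "terminase", "outdir", "seed", "stages", "min_cov", "max_evalue",
  "inflation", "scales", "n_boot", "linkage", "au_threshold",
  "size_class_bounds", "min_aa", "dnds_B", "dnds_alpha")

pv_all_stages <- c("io", "homology", "pangenome", "classify", "codon",
                   "phylo", "selection", "hostrange", "growth")

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; defaults are filled in for tunables.
#'
#' @param ... configuration entries (see Details) or a single named
#'   list.
#' @details Required: `fasta`, `annotation`, `outdir`. Optional inputs:
#'   `cohort`, `host_range`, `isolates`, `growth`, `terminase` (a
#'   labeled-reference protein FASTA whose reference headers carry
#'   `strategy=<label> role=reference`). Tunables: `seed` (1), `stages`
#'   (all), `min_cov` (0.75), `max_evalue` (1e-5), `inflation` (1.5),
#'   `scales`, `n_boot` (1000), `linkage` ("average"), `au_threshold`
#'   (0.95), `size_class_bounds` (c(1e5, 2e5)), `min_aa` (50), `dnds_B`
#'   (1000), `dnds_alpha` (0.05).
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && is.list(args[[1]])) {
    args <- args[[1]]
  }
  unknown <- setdiff(names(args), pv_config_keys)
  pv_assert(length(unknown) == 0,
            sprintf("unknown config key(s): %s",
                    paste(unknown, collapse = ", ")),
            "panvirome_validation_error")
  defaults <- list(seed = 1L, stages = pv_all_stages, min_cov = 0.75,
                   max_evalue = 1e-5, inflation = 1.5,
                   scales = seq(0.5, 1.4, by = 0.1), n_boot = 1000,
                   linkage = "average", au_threshold = 0.95,
                   size_class_bounds = c(1e5, 2e5), min_aa = 50L,
                   dnds_B = 1000, dnds_alpha = 0.05)
  cfg <- utils::modifyList(defaults, args)
  pv_assert(!is.null(cfg$fasta) && !is.null(cfg$outdir),
            "config needs at least fasta and outdir")
  pv_assert(all(cfg$stages %in% pv_all_stages),
            sprintf("unknown stage(s): %s",
                    paste(setdiff(cfg$stages, pv_all_stages),
                          collapse = ", ")),
            "panvirome_validation_error")
  structure(cfg, class = "pipeline_config")
}

pv_read_terminase <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  seqs <- setNames(as.character(set), ids)
  is_ref <- grepl("role=reference", full)
  labels <- sub(".*strategy=(\\S+).*", "\\1", full[is_ref])
  names(labels) <- ids[is_ref]
  list(seqs = seqs, labels = labels)
}

pv_write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list (also written as
#'   `summary.json`). A stage failure raises a structured error naming
#'   the stage; outputs of completed stages remain on disk.
#' @export
run_pipeline <- function(config) {
  pv_assert(inherits(config, "pipeline_config"),
            "config must come from pipeline_config()")
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = cfg$seed, stages = cfg$stages)
  stage <- function(name, body) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[panvirome] stage %s ...", name))
    res <- tryCatch(body(), error = function(e) {
      pv_stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
              "panvirome_stage_error")
    })
    message(sprintf("[panvirome] stage %s done (%.1fs)", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  env <- new.env()

  stage("io", function() {
    env$genomes <- read_genomes(cfg$fasta, cfg$annotation, cfg$cohort)
    if (!is.null(cfg$cohort)) {
      env$cohort <- read_cohort_table(cfg$cohort,
                                      bounds = cfg$size_class_bounds)
    } else {
      env$cohort <- data.frame(
        genome_id = vapply(env$genomes, `[[`, "", "id"),
        size_bp = vapply(env$genomes, `[[`, 0L, "length_bp"),
        cds_count = vapply(env$genomes, function(g) nrow(g$cds), 0L),
        trna_count = vapply(env$genomes, `[[`, 0L, "trna_count"),
        gc_percent = vapply(env$genomes, `[[`, 0, "gc_percent"),
        integrase = vapply(env$genomes, `[[`, "", "integrase_flag"),
        stringsAsFactors = FALSE, row.names = NULL)
      env$cohort$size_class <- vapply(env$cohort$size_bp, size_class, "",
                                      bounds = cfg$size_class_bounds)
    }
    gc_sum <- summarize_by_class(env$cohort, "gc_percent", "size_class")
    size_sum <- summarize_by_class(env$cohort, "size_bp", "size_class")
    pv_write_tsv(env$cohort, file.path(cfg$outdir, "cohort_table.tsv"))
    summary$cohort <<- list(
      n_genomes = nrow(env$cohort),
      n_size_classes = length(unique(env$cohort$size_class)),
      total_cds = sum(env$cohort$cds_count),
      gc_by_class = gc_sum, size_by_class = size_sum)
  })

  stage("homology", function() {
    env$hits <- all_vs_all(env$genomes, min_cov = cfg$min_cov,
                           max_evalue = cfg$max_evalue)
    bbh <- bbh_graph(env$hits)
    cog <- cog_triangles(bbh, env$hits$loci)
    mcl <- mcl_cluster(env$hits, inflation = cfg$inflation)
    env$clusters <- intersect_clusterings(cog, mcl)
    env$idmat <- identity_matrix(env$hits)
    cl_df <- do.call(rbind, lapply(names(env$clusters$clusters),
                                   function(cid) {
      m <- env$clusters$clusters[[cid]]
      data.frame(cluster_id = cid, genome = m$genome, locus = m$locus,
                 stringsAsFactors = FALSE)
    }))
    pv_write_tsv(cl_df, file.path(cfg$outdir, "clusters.tsv"))
    summary$homology <<- list(n_hits = nrow(env$hits$hits),
                              n_bbh = nrow(bbh),
                              n_cog = length(cog$clusters),
                              n_mcl = length(mcl$clusters),
                              n_intersection = length(env$clusters$clusters))
  })

  stage("pangenome", function() {
    env$pan <- build_matrix(env$clusters,
                            vapply(env$genomes, `[[`, "", "id"))
    write_pan_matrix(env$pan, file.path(cfg$outdir, "pan_matrix.tsv"))
    summary$pangenome <<- list(
      n_clusters = ncol(env$pan),
      core_all = length(core_genome(env$pan, rownames(env$pan))))
  })

  stage("classify", function() {
    env$tree <- multiscale_bootstrap(env$pan, scales = cfg$scales,
                                     n_boot = cfg$n_boot,
                                     linkage = cfg$linkage,
                                     seed = cfg$seed)
    env$groups <- cut_groups(env$tree, cfg$au_threshold)
    write_cluster_tree(env$tree, file.path(cfg$outdir, "tree.nwk"))
    pv_write_tsv(data.frame(genome_id = names(env$groups),
                            group = unname(env$groups),
                            stringsAsFactors = FALSE),
                 file.path(cfg$outdir, "groups.tsv"))
    summary$classify <<- list(n_groups = length(unique(env$groups)),
                              groups = as.list(env$groups))
  })

  stage("codon", function() {
    env$profiles <- lapply(env$genomes, codon_profile)
    pca <- codon_pca(env$profiles, "rscu")
    assoc <- trna_gc_association(env$cohort)
    pv_write_tsv(data.frame(genome_id = rownames(pca$scores),
                            pca$scores[, seq_len(min(3, ncol(pca$scores))),
                                       drop = FALSE],
                            stringsAsFactors = FALSE),
                 file.path(cfg$outdir, "rscu_pca.tsv"))
    summary$codon <<- list(
      pc1_explained = pca$explained[1],
      trna_gc_perfect_separation = assoc$perfect_separation,
      trna_gc_r = assoc$r,
      outliers = flag_outlier(env$profiles, pca$scores))
  })

  stage("phylo", function() {
    if (is.null(cfg$terminase)) return(invisible(NULL))
    term <- pv_read_terminase(cfg$terminase)
    aln <- align_proteins(term$seqs)
    tree <- nj_tree(p_distance_matrix(aln))
    calls <- infer_packaging(tree, term$labels)
    pd <- p_distance_matrix(aln)
    pat <- patristic(tree)
    ut <- upper.tri(pd)
    sat <- saturation_test(pd[ut], pat[rownames(pd), colnames(pd)][ut])
    ape::write.tree(tree, file.path(cfg$outdir, "terminase.nwk"))
    pv_write_tsv(calls, file.path(cfg$outdir, "packaging.tsv"))
    summary$phylo <<- list(
      packaging = setNames(as.list(calls$strategy), calls$query),
      saturated = sat$saturated, saturation_r2 = sat$r_squared)
  })

  stage("selection", function() {
    big <- Filter(function(m) nrow(m) >= 4, env$clusters$clusters)
    res <- list()
    for (cid in names(big)) {
      m <- big[[cid]]
      nts <- setNames(vapply(seq_len(nrow(m)), function(k) {
        g <- env$genomes[[m$genome[k]]]
        g$cds$nt_seq[g$cds$locus_id == m$locus[k]]
      }, ""), m$locus)
      aln <- codon_align(nts)
      bps <- if (length(nts) >= 4) detect_breakpoints(aln) else integer(0)
      dd <- cluster_dnds(aln, boundaries = bps, B = cfg$dnds_B,
                         seed = cfg$seed, alpha = cfg$dnds_alpha)
      dd$cluster_id <- cid
      res[[cid]] <- dd
    }
    if (length(res)) {
      tab <- do.call(rbind, res)
      pv_write_tsv(tab, file.path(cfg$outdir, "selection.tsv"))
      summary$selection <<- list(
        n_clusters_tested = length(res),
        positively_selected =
          unique(tab$cluster_id[tab$positively_selected]))
    } else {
      summary$selection <<- list(n_clusters_tested = 0L,
                                 positively_selected = character(0))
    }
  })

  stage("hostrange", function() {
    if (is.null(cfg$host_range)) return(invisible(NULL))
    m <- encode_matrix(cfg$host_range, cfg$isolates)
    br <- vapply(rownames(m$scores), function(p) breadth(m, p), 0L)
    lys <- vapply(br, assign_lysotype_group, "",
                  n_isolates = ncol(m$scores))
    pv_write_tsv(data.frame(phage_id = names(br), breadth = unname(br),
                            lysotype = unname(lys),
                            stringsAsFactors = FALSE),
                 file.path(cfg$outdir, "lysotypes.tsv"))
    summary$hostrange <<- list(breadth = as.list(br),
                               lysotype = as.list(lys))
    if (!is.null(m$isolates) &&
        length(unique(m$isolates$lifestyle)) == 2) {
      ls <- lifestyle_split(m)
      summary$hostrange$lifestyle_fisher_p <<- ls$fisher_p
      summary$hostrange$n_mesophilic_exceptions <<- nrow(ls$exceptions)
    }
  })

  stage("growth", function() {
    if (is.null(cfg$growth)) return(invisible(NULL))
    curves <- read_growth_curves(cfg$growth)
    est <- lapply(curves, estimate_burst)
    df <- data.frame(phage_id = names(curves),
                     burst = vapply(est, `[[`, 0, "burst"),
                     latent_min = vapply(est, `[[`, 0, "latent_min"),
                     stringsAsFactors = FALSE, row.names = NULL)
    pv_write_tsv(df, file.path(cfg$outdir, "growth_estimates.tsv"))
    summary$growth <<- list(burst = setNames(as.list(df$burst),
                                             df$phage_id),
                            latent_min = setNames(as.list(df$latent_min),
                                                  df$phage_id))
  })

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(cfg$outdir, "summary.json"))
  invisible(summary)
}
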