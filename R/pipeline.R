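# End-to-end orchestration of the synthetic study: simulation ->
# orthology -> branch scan -> expression -> enrichment -> report.  All
# randomness flows from the single config seed through named per-stage
# substreams; identical config + seed gives byte-identical outputs.

#' Build a pipeline run configuration
#'
#' Key-value configuration of an end-to-end synthetic run.  The
#' configuration round-trips losslessly through its serialized form
#' (\code{\link{write_config}} / \code{\link{read_config}}).
#'
#' @param seed master seed; every stage derives its own substream.
#' @param n_taxa,tree_depth phylogeny size and typical branch length.
#' @param foreground node labels of the branches to scan.
#' @param n_genes_scan,n_codons genes entering the selection scan and
#'   their alignment length.
#' @param frac_selected fraction of scan genes simulated under positive
#'   selection (omega2 = \code{omega2}); the rest are null genes.
#' @param kappa,omega0,omega2,p0,p1 generating branch-site parameters.
#' @param n_genes_expr,n_psg_expr,q1_prob expression-simulation size, PSG
#'   set size and quadrant-I planting probability; the simulated PSG set
#'   stands in for the multi-branch PSG union of a full-size study.
#' @param candidate_q,de_q,posterior_threshold decision thresholds.
#' @param n_starts optimization starts per model fit.
#' @param n_genes_catalog,n_species_catalog,catalog_divergence orthology-
#'   stage catalog simulation.
#' @param n_terms annotation terms for the enrichment stage.
#' @param stages stages to run, a subset of
#'   \code{c("simulate", "orthologs", "scan", "expression", "enrich")}.
#' @param out_dir output directory (NULL = nothing written).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1, n_taxa = 6, tree_depth = 0.08,
                       foreground = "t1", n_genes_scan = 12, n_codons = 300,
                       frac_selected = 0.25, kappa = 2, omega0 = 0.2,
                       omega2 = 8, p0 = 0.4, p1 = 0.4, n_genes_expr = 1500,
                       n_psg_expr = 40, q1_prob = 0.8, candidate_q = 0.1,
                       de_q = 0.1, posterior_threshold = 0.5, n_starts = 2,
                       n_genes_catalog = 12, n_species_catalog = 3,
                       catalog_divergence = 0.05, n_terms = 15,
                       stages = c("simulate", "orthologs", "scan",
                                  "expression", "enrich"),
                       out_dir = NULL) {
  cfg <- as.list(environment())
  schema <- config_schema()
  for (k in names(cfg)) {
    if (!is.null(cfg[[k]])) {
      cfg[[k]] <- switch(schema[[k]],
                         integer = as.integer(cfg[[k]]),
                         numeric = as.numeric(cfg[[k]]),
                         character = as.character(cfg[[k]]))
    }
  }
  stopifnot(cfg$candidate_q > 0, cfg$candidate_q <= 1, cfg$de_q > 0,
            cfg$de_q <= 1, cfg$posterior_threshold > 0,
            cfg$posterior_threshold <= 1,
            all(stages %in% c("simulate", "orthologs", "scan",
                              "expression", "enrich")))
  structure(cfg, class = "run_config")
}

config_schema <- function() {
  c(seed = "integer", n_taxa = "integer", tree_depth = "numeric",
    foreground = "character", n_genes_scan = "integer",
    n_codons = "integer", frac_selected = "numeric", kappa = "numeric",
    omega0 = "numeric", omega2 = "numeric", p0 = "numeric", p1 = "numeric",
    n_genes_expr = "integer", n_psg_expr = "integer", q1_prob = "numeric",
    candidate_q = "numeric", de_q = "numeric",
    posterior_threshold = "numeric", n_starts = "integer",
    n_genes_catalog = "integer", n_species_catalog = "integer",
    catalog_divergence = "numeric", n_terms = "integer",
    stages = "character", out_dir = "character")
}

#' Serialize / restore a run configuration
#'
#' Plain-text \code{key = value} form, one key per line; vector values
#' are comma-joined.
#'
#' @param config a \code{\link{run_config}}.
#' @param path file path.
#' @return \code{read_config} returns the restored \code{run_config}.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config_schema()), function(k) {
    v <- config[[k]]
    paste0(k, " = ", if (is.null(v)) "" else paste(v, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  schema <- config_schema()
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, " = ", fixed = TRUE)[[1]]
    k <- kv[1]
    raw <- if (length(kv) < 2) "" else kv[2]
    if (!(k %in% names(schema))) next
    v <- if (!nzchar(raw)) {
      NULL
    } else {
      parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
      switch(schema[[k]],
             integer = as.integer(parts),
             numeric = as.numeric(parts),
             character = parts)
    }
    vals[[k]] <- v
  }
  do.call(run_config, vals)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in order on fully synthetic inputs with
#' known ground truth: simulates the phylogeny, per-gene codon
#' alignments (a configurable fraction under positive selection on the
#' foreground branch), CDS catalogs and two-species aging count
#' matrices; assigns orthologs by reciprocal best hit; scans each
#' foreground branch with the branch-site test (FDR candidates plus
#' control reruns); runs the differential-expression, quadrant and
#' directionality stage; and tests synthetic annotation terms for PSG
#' enrichment.  When \code{out_dir} is set every stage writes its tables
#' (with threshold headers) plus a machine-readable \code{summary.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @return The run report (named list), invisibly when written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("psgscan")),
                 seed = config$seed,
                 thresholds = list(candidate_q = config$candidate_q,
                                   de_q = config$de_q,
                                   posterior = config$posterior_threshold))
  stage <- function(name) name %in% config$stages
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (stage("simulate")) run_stage("simulate", function() {
    tree <- simulate_tree(config$n_taxa, config$tree_depth,
                          seed = derive_seed(config$seed, 11))
    tree <- set_foreground(tree, config$foreground[1])
    state$tree <- tree
    n <- config$n_genes_scan
    k <- round(config$frac_selected * n)
    genes <- sprintf("g%04d", seq_len(n))
    par_alt <- branch_site_params(kappa = config$kappa,
                                  omega0 = config$omega0,
                                  omega2 = config$omega2, p0 = config$p0,
                                  p1 = config$p1)
    par_null <- branch_site_params(kappa = config$kappa,
                                   omega0 = config$omega0, omega2 = 1,
                                   p0 = config$p0, p1 = config$p1)
    alns <- vector("list", n)
    for (i in seq_len(n)) {
      sim <- simulate_codon_alignment(tree,
                                      if (i <= k) par_alt else par_null,
                                      config$n_codons,
                                      seed = derive_seed(config$seed,
                                                         200 + i))
      alns[[i]] <- sim$alignment
    }
    names(alns) <- genes
    state$alignments <- alns
    state$true_selected <- genes[seq_len(k)]
    cat_sim <- simulate_cds_catalog(config$n_genes_catalog,
                                    config$n_species_catalog,
                                    isoforms_per_gene = 2,
                                    divergence = config$catalog_divergence,
                                    seed = derive_seed(config$seed, 31))
    state$catalog <- cat_sim$catalog
    state$catalog_truth <- cat_sim$truth
    spec <- count_sim_spec(n_genes = config$n_genes_expr,
                           n_psg = config$n_psg_expr,
                           q1_prob = config$q1_prob,
                           seed = derive_seed(config$seed, 41))
    cs <- simulate_counts(spec)
    # the count simulation's PSG set stands in for the (much larger)
    # multi-branch PSG union of a full-size study
    state$counts <- cs
    report$simulate <<- list(n_genes_scan = n, n_true_selected = k,
                             n_genes_expr = config$n_genes_expr)
    if (!is.null(out)) {
      write_newick(tree, file.path(out, "tree.nwk"))
      dir.create(file.path(out, "alignments"), showWarnings = FALSE)
      for (g in genes) {
        write_alignment_fasta(alns[[g]],
                              file.path(out, "alignments",
                                        paste0(g, ".fasta")))
      }
      write_counts(cs$counts_a, file.path(out, "counts_a.tsv"))
      write_counts(cs$counts_b, file.path(out, "counts_b.tsv"))
      write_result_table(cs$truth, file.path(out, "expression_truth.tsv"),
                         list(q1_prob = config$q1_prob))
    }
  })

  if (stage("orthologs")) run_stage("orthologs", function() {
    groups <- lapply(assign_orthologs(state$catalog, anchor = "sp1"),
                     select_isoforms)
    state$groups <- groups
    truth <- state$catalog_truth
    recovered <- vapply(names(groups), function(g) {
      all(vapply(setdiff(unique(truth$species), "sp1"), function(sp) {
        sp %in% names(groups[[g]]$chosen) &&
          groups[[g]]$chosen[[sp]]$gene == g
      }, logical(1)))
    }, logical(1))
    report$orthologs <<- list(n_groups = length(groups),
                              recovery = mean(recovered))
    if (!is.null(out)) {
      manifest <- do.call(rbind, lapply(groups, function(gr) {
        data.frame(group = gr$anchor_gene,
                   species = names(gr$chosen),
                   gene = vapply(gr$chosen, function(r) r$gene, ""),
                   isoform = vapply(gr$chosen, function(r) r$isoform, ""))
      }))
      write_result_table(manifest, file.path(out, "ortholog_manifest.tsv"))
    }
  })

  if (stage("scan")) run_stage("scan", function() {
    scans <- lapply(seq_along(config$foreground), function(i) {
      scan_branch(state$alignments, state$tree, config$foreground[i],
                  q_threshold = config$candidate_q,
                  n_starts = config$n_starts,
                  seed = derive_seed(config$seed, 50 + i))
    })
    state$scans <- scans
    un <- union_psgs(scans)
    state$psgs <- un$psgs
    report$scan <<- list(
      branches = config$foreground,
      tested = sum(vapply(scans, function(s) s$counts[["tested"]], 0)),
      candidates = sum(vapply(scans, function(s) s$counts[["candidates"]],
                              0)),
      psgs_union = length(un$psgs),
      multi_branch = nrow(un$multi_branch))
    if (!is.null(out)) {
      for (s in state$scans) {
        write_result_table(s$records,
                           file.path(out, paste0("scan_", s$branch,
                                                 ".tsv")),
                           list(candidate_q = config$candidate_q))
      }
      write_result_table(data.frame(gene = un$psgs),
                         file.path(out, "psg_union.tsv"),
                         list(candidate_q = config$candidate_q))
    }
  })

  if (stage("expression")) run_stage("expression", function() {
    de_a <- de_test(state$counts$counts_a, q_threshold = config$de_q)
    de_b <- de_test(state$counts$counts_b, q_threshold = config$de_q)
    psg_set <- state$counts$truth$gene[state$counts$truth$psg]
    qt <- classify_quadrants(de_a, de_b, psg_set)
    state$de_a <- de_a
    state$de_b <- de_b
    state$psg_expr <- psg_set
    dir_test <- directionality_test(de_a, de_b, psg_set)
    report$expression <<- list(
      regulated_a = sum(de_a$regulated), regulated_b = sum(de_b$regulated),
      regulated_both = nrow(qt),
      quadrant_counts = as.integer(table(qt$quadrant)),
      quadrant_fisher_p = quadrant_fisher(qt),
      directionality_p = dir_test$p_value)
    if (!is.null(out)) {
      write_result_table(de_a, file.path(out, "de_species_a.tsv"),
                         list(de_q = config$de_q))
      write_result_table(de_b, file.path(out, "de_species_b.tsv"),
                         list(de_q = config$de_q))
      write_result_table(as.data.frame(qt),
                         file.path(out, "quadrants.tsv"),
                         list(de_q = config$de_q))
    }
  })

  if (stage("enrich")) run_stage("enrich", function() {
    genes <- state$de_a$gene
    ann <- with_seed(derive_seed(config$seed, 71), {
      terms <- sprintf("T%03d", seq_len(config$n_terms))
      n_per <- pmin(rbinom(length(genes), 3, 0.5) + 1, config$n_terms)
      g <- rep(genes, n_per)
      t <- unlist(lapply(n_per, function(k) sample(terms, k)))
      annotation_map(g, t, universe = genes)
    })
    psgs_here <- intersect(state$psg_expr, ann$universe)
    enr <- hypergeom_enrich(psgs_here, ann, q_threshold = config$de_q)
    lfc <- setNames(state$de_a$lfc, state$de_a$gene)
    fc <- fc_set_test(lfc, ann, q_threshold = config$de_q)
    report$enrich <<- list(n_terms = nrow(enr),
                           n_significant = sum(enr$significant),
                           fc_significant = sum(fc$significant))
    if (!is.null(out)) {
      write_result_table(enr, file.path(out, "enrichment.tsv"),
                         list(q = config$de_q))
      write_result_table(fc, file.path(out, "fc_set_test.tsv"),
                         list(q = config$de_q))
    }
  })

  if (!is.null(out)) {
    write_config(config, file.path(out, "config.txt"))
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, file.path(out, "summary.json"))
    return(invisible(report))
  }
  report
}
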