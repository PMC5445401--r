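#' Default pipeline configuration
#'
#' A single declarative configuration covering every stage. Any field can be
#' overridden by supplying a partial list (or a YAML file) to
#' [run_pipeline()].
#'
#' @param seed Global seed; every stochastic stage draws from it.
#' @return A nested list of stage settings.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    paths = list(out_dir = NULL, matrix = NULL, samples = NULL),
    simulation = list(n_probes = 2000L, planted_block_size = 16L,
                      ct_effect = 4, nt_effect = 0.25,
                      baseline_log_mean = 5.5, baseline_log_sd = 1,
                      noise_log_sd = 0.3),
    genesets = list(threshold = 2, mode = "signed", per_line = FALSE),
    cluster = list(variant = "ward.D2", k = 2L,
                   lines = "flagged"),  # "flagged" or "all"
    de = list(group_a_line = "MT1E-CT", group_b_line = "MT1E",
              n_perm = 1000L),
    growth = list(min_window = 3L, n_replicates = 3L, noise_sd = 0.01,
                  t_points = seq(0, 168, by = 24), lag = 24,
                  plateau_level = 2.5,
                  line_td = c(parent = 32.5, blank_vector = 39.5,
                              MT1E = 35.8, MT3 = 53.1, MT3dNT = 57.3,
                              MT3dCT = 64.7, "MT1E-NT" = 60.9,
                              "MT1E-CT" = 55.2)),
    phenotype = list(n_fields = 21L, n_flasks = 3L, ter_mean = 40,
                     ter_sd = 8, dome_rate_positive = 2.7)
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  merge_config(default_config(), config)
}

write_tsv_atomic <- function(tbl, path) {
  write_atomic(path, function(p) readr::write_tsv(tbl, p, progress = FALSE))
}

write_json_atomic <- function(x, path) {
  write_atomic(path, function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a shared output directory:
#' `simulate` writes the synthetic study (expression matrix, sample sheet,
#' truth, growth curves, phenotype tables); `genesets` builds the
#' fold-change gene sets; `cluster` computes the overlap-distance matrix,
#' Ward tree, Newick export and k-cut; `de` runs the permutation
#' differential-expression test between two configured lines; `growth`
#' estimates doubling times per line and compares them; `phenotype`
#' summarises dome counts and TER and tests the dome--expression
#' association. `"all"` runs everything in order. Outputs are written
#' atomically (temp file then rename) and a `run_metadata.json` records the
#' seed, configuration hash and stage list.
#'
#' @param config A nested list of overrides, or a YAML file path; see
#'   [default_config()].
#' @param stages Character vector of stage names, or `"all"`.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$paths$out_dir`.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config = list(), stages = "all", out_dir = NULL) {
  cfg <- read_config(config)
  known <- c("simulate", "genesets", "cluster", "de", "growth", "phenotype")
  if (identical(stages, "all")) stages <- known
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", "),
                 "; valid: ", paste(c(known, "all"), collapse = ", ")))
  }
  out_dir <- out_dir %||% cfg$paths$out_dir %||%
    abort("an output directory is required (out_dir or config$paths$out_dir)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  pth <- function(f) file.path(out_dir, f)

  log_msg <- function(...) {
    inform(paste0("[ohclust] ", paste0(...)))
  }

  load_study <- function() {
    mpath <- cfg$paths$matrix %||% pth("expression.tsv")
    spath <- cfg$paths$samples %||% pth("samples.tsv")
    if (!file.exists(mpath)) abort(paste0("expression matrix not found: ", mpath))
    if (!file.exists(spath)) abort(paste0("sample sheet not found: ", spath))
    list(expression = read_expression_matrix(mpath),
         samples = read_sample_sheet(spath))
  }

  if ("simulate" %in% stages) {
    log_msg("simulate: seed ", cfg$seed)
    scfg <- sim_config(n_probes = cfg$simulation$n_probes,
                       planted_block_size = cfg$simulation$planted_block_size,
                       ct_effect = cfg$simulation$ct_effect,
                       nt_effect = cfg$simulation$nt_effect,
                       baseline_log_mean = cfg$simulation$baseline_log_mean,
                       baseline_log_sd = cfg$simulation$baseline_log_sd,
                       noise_log_sd = cfg$simulation$noise_log_sd,
                       seed = cfg$seed)
    sim <- simulate_expression(scfg)
    paths$expression <- write_tsv_atomic(sim$expression, pth("expression.tsv"))
    paths$samples <- write_tsv_atomic(sim$samples, pth("samples.tsv"))
    paths$truth <- write_json_atomic(
      list(block = attr(sim$truth, "block"),
           folds = sim$truth), pth("truth.json"))

    g <- cfg$growth
    curves <- purrr::imap(g$line_td, function(td, line) {
      purrr::map(seq_len(g$n_replicates), function(r) {
        simulate_growth(td, g$t_points, lag = g$lag,
                        plateau_level = g$plateau_level,
                        noise_sd = g$noise_sd, n_wells = 3L,
                        seed = cfg$seed + 7L * r +
                          97L * match(line, names(g$line_td))) %>%
          mutate(cell_line = line, replicate = r)
      }) %>% bind_rows()
    }) %>% bind_rows()
    paths$growth_curves <- write_tsv_atomic(curves, pth("growth_curves.tsv"))

    ph <- cfg$phenotype
    lines <- default_lines()
    dome_pos <- lines$has_ct & !lines$has_nt   # C-terminal induces domes
    phen <- purrr::map(seq_len(nrow(lines)), function(i) {
      p <- simulate_phenotype(
        dome_rate = if (dome_pos[i]) ph$dome_rate_positive else 0,
        n_fields = ph$n_fields, n_flasks = ph$n_flasks,
        ter_mean = ph$ter_mean, ter_sd = ph$ter_sd,
        seed = cfg$seed + 11L * i)
      list(domes = mutate(p$domes, cell_line = lines$name[i]),
           ter = mutate(p$ter, cell_line = lines$name[i]))
    })
    paths$domes <- write_tsv_atomic(bind_rows(purrr::map(phen, "domes")),
                                    pth("domes.tsv"))
    paths$ter <- write_tsv_atomic(bind_rows(purrr::map(phen, "ter")),
                                  pth("ter.tsv"))
  }

  if ("genesets" %in% stages) {
    log_msg("genesets: threshold ", cfg$genesets$threshold,
            ", mode ", cfg$genesets$mode)
    st <- load_study()
    sets <- build_gene_sets(st$expression, st$samples,
                            threshold = cfg$genesets$threshold,
                            mode = cfg$genesets$mode,
                            per_line = isTRUE(cfg$genesets$per_line))
    paths$gene_sets <- write_tsv_atomic(sets, pth("gene_sets.tsv"))
    write_json_atomic(list(threshold = attr(sets, "threshold"),
                           mode = attr(sets, "mode"),
                           set_ids = attr(sets, "set_ids")),
                      pth("gene_sets_meta.json"))
    paths$gene_sets_meta <- pth("gene_sets_meta.json")
  }

  if ("cluster" %in% stages) {
    log_msg("cluster: Ward variant ", cfg$cluster$variant)
    st <- load_study()
    sets <- readr::read_tsv(pth("gene_sets.tsv"), show_col_types = FALSE,
                            progress = FALSE)
    meta <- jsonlite::read_json(pth("gene_sets_meta.json"), simplifyVector = TRUE)
    keep_ids <- meta$set_ids
    if (identical(cfg$cluster$lines, "flagged")) {
      flagged <- st$samples$array_id[st$samples$has_ct | st$samples$has_nt]
      keep_ids <- intersect(keep_ids, flagged)
    }
    D <- gene_set_distance(sets, set_ids = keep_ids)
    paths$distance <- write_distance_matrix(D, pth("distance_matrix.tsv"))
    tree <- ward_agglomerate(D, variant = cfg$cluster$variant)
    paths$merges <- write_tsv_atomic(tidy(tree), pth("merges.tsv"))
    paths$newick <- write_atomic(pth("dendrogram.nwk"),
                                 function(p) writeLines(to_newick(tree), p))
    paths$clusters <- write_tsv_atomic(cut_tree(tree, cfg$cluster$k),
                                       pth("clusters.tsv"))
  }

  if ("de" %in% stages) {
    st <- load_study()
    ga <- st$samples$array_id[st$samples$cell_line == cfg$de$group_a_line]
    gb <- st$samples$array_id[st$samples$cell_line == cfg$de$group_b_line]
    log_msg("de: ", cfg$de$group_a_line, " (", length(ga), ") vs ",
            cfg$de$group_b_line, " (", length(gb), ")")
    fit <- sam_test(st$expression, ga, gb, n_perm = cfg$de$n_perm,
                    seed = cfg$seed)
    paths$sam <- write_tsv_atomic(tidy(fit), pth("sam_results.tsv"))
    paths$sam_meta <- write_json_atomic(
      list(s0 = fit$s0, n_perm = fit$n_perm, mode = fit$mode,
           seed = cfg$seed, group_a = ga, group_b = gb),
      pth("sam_meta.json"))
  }

  if ("growth" %in% stages) {
    log_msg("growth: doubling-time estimation")
    curves <- readr::read_tsv(pth("growth_curves.tsv"),
                              show_col_types = FALSE, progress = FALSE)
    est <- curves %>%
      group_by(.data$cell_line, .data$replicate) %>%
      dplyr::group_modify(function(d, key) {
        tidy(doubling_time(d, min_window = cfg$growth$min_window))
      }) %>% ungroup()
    paths$doubling_times <- write_tsv_atomic(est, pth("doubling_times.tsv"))
    cmp <- compare_doubling_times(est)
    paths$growth_anova <- write_tsv_atomic(glance(cmp), pth("growth_anova.tsv"))
    paths$growth_tukey <- write_tsv_atomic(tidy(cmp), pth("growth_tukey.tsv"))
  }

  if ("phenotype" %in% stages) {
    log_msg("phenotype: dome / TER summaries and association")
    domes <- readr::read_tsv(pth("domes.tsv"), show_col_types = FALSE,
                             progress = FALSE)
    ter <- readr::read_tsv(pth("ter.tsv"), show_col_types = FALSE,
                           progress = FALSE)
    dsum <- dome_summary(domes, n_fields = cfg$phenotype$n_fields)
    tsum <- ter_summary(ter)
    paths$dome_summary <- write_tsv_atomic(dsum, pth("dome_summary.tsv"))
    paths$ter_daily <- write_tsv_atomic(tsum$daily, pth("ter_daily.tsv"))
    paths$ter_combined <- write_tsv_atomic(tsum$combined, pth("ter_combined.tsv"))

    st <- load_study()
    truth <- jsonlite::read_json(pth("truth.json"), simplifyVector = TRUE)
    block <- truth$block
    expr_block <- st$expression %>% filter(.data$probe_id %in% block)
    line_expr <- st$samples %>%
      filter(!.data$is_reference) %>%
      group_by(.data$cell_line) %>%
      summarise(set_expression = mean(log(
        as.matrix(expr_block[, .data$array_id, drop = FALSE]))),
        .groups = "drop")
    assoc_in <- dsum %>%
      select("cell_line", "dome_positive") %>%
      dplyr::inner_join(line_expr, by = "cell_line")
    assoc <- dome_geneset_association(assoc_in)
    paths$association <- write_tsv_atomic(assoc, pth("association.tsv"))
  }

  meta <- list(seed = cfg$seed, stages = stages,
               config_hash = rlang::hash(cfg),
               tool = "ohclust",
               version = as.character(utils::packageVersion("ohclust")))
  paths$metadata <- write_json_atomic(meta, pth("run_metadata.json"))
  invisible(paths)
}
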