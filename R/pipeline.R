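default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    msa = list(simulate = list()),      # or list(path=, format=, ref_id=)
    curation = list(enabled = TRUE, identity_threshold = 0.95,
                    min_length_fraction = 0.7),
    sca = list(pseudocount = NULL, min_sub_fraction = 0.25,
               min_sub_rows = 100L, max_gap_fraction = 0.5, k_sectors = 3L),
    network = list(threshold = 1.0, hub_min_degree = 9L),
    structure = list(simulate = list(motif = "random-coil")),
    kinetics = NULL                      # list(titrations=, manifest=, ...)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- utils::modifyList(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full allostery-wiring pipeline
#'
#' Orchestrates curation, SCA, network construction, structural mapping and
#' double-mutant-cycle kinetics from a single configuration, in dependency
#' order, and produces a consolidated report (JSON machine summary plus
#' Markdown human summary when `out_dir` is set). The run is deterministic
#' given the configuration and its seeds; the report embeds a hash of the
#' resolved configuration for provenance.
#'
#' @param config A configuration list or path to a YAML file. Recognised
#'   entries (all optional, defaults in place): `seed`; `out_dir`;
#'   `msa` (either `simulate` args for [msa_sim_spec()] or `path` / `format` /
#'   `ref_id`); `curation` (`enabled`, `identity_threshold`,
#'   `min_length_fraction`); `sca` (pseudocount / admissibility / gap
#'   parameters and `k_sectors`); `network` (`threshold`, `hub_min_degree`);
#'   `structure` (`path` / `chain` / `offset`, or `simulate` with
#'   `n_residues`, `motif`); `kinetics` (`titrations` and `manifest` as paths
#'   or data frames, `temperature`, `additivity_bound`).
#' @return A list of class `kinwire_report`: per-stage results (`curation`,
#'   `sca`, `sectors`, `network`, `structure`, `cycles`), the resolved
#'   `config`, its `config_hash`, and a `summary` list of headline numbers.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  for (f in c(cfg$msa$path, cfg$structure$path,
              if (is.character(cfg$kinetics$titrations)) cfg$kinetics$titrations,
              if (is.character(cfg$kinetics$manifest)) cfg$kinetics$manifest)) {
    if (!is.null(f) && !file.exists(f)) abort(paste0("input file not found: ", f))
  }
  cfg_for_hash <- cfg
  cfg_for_hash$out_dir <- NULL   # provenance hash is location-independent
  report <- list(config = cfg, config_hash = rlang::hash(cfg_for_hash))

  msa_stage <- run_stage("msa", {
    if (!is.null(cfg$msa$path)) {
      list(aln = read_msa(cfg$msa$path, format = cfg$msa$format %||% "fasta",
                          ref_id = cfg$msa$ref_id),
           truth = NULL)
    } else {
      sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$msa$simulate)
      sim <- simulate_msa(do.call(msa_sim_spec, sim_args))
      list(aln = sim$alignment, truth = sim$truth)
    }
  })
  aln <- msa_stage$aln
  truth <- msa_stage$truth

  if (isTRUE(cfg$curation$enabled)) {
    cur <- run_stage("curation", {
      seqs <- tibble(id = aln$ids,
                     residues = apply(aln$mat, 1, paste0, collapse = ""))
      curate_sequences(seqs, cfg$curation$identity_threshold,
                       cfg$curation$min_length_fraction, aligned = TRUE)
    })
    report$curation <- glance.curation_report(cur$report)
    ref_kept <- if (!is.null(aln$ref_id) && aln$ref_id %in% cur$kept$id) {
      aln$ref_id
    } else if (nrow(cur$kept)) cur$kept$id[[1]] else NULL
    aln <- aa_alignment(cur$kept, ref_id = ref_kept)
  }

  cm <- run_stage("sca", {
    sca_coupling(aln, pseudocount = cfg$sca$pseudocount,
                 min_sub_fraction = cfg$sca$min_sub_fraction,
                 min_sub_rows = cfg$sca$min_sub_rows,
                 max_gap_fraction = cfg$sca$max_gap_fraction)
  })
  report$sca <- cm

  sectors <- run_stage("sectors", {
    tryCatch(extract_sectors(cm, threshold = cfg$network$threshold,
                             k_sectors = cfg$sca$k_sectors),
             error = function(e) NULL)
  })
  report$sectors <- sectors

  net <- run_stage("network", {
    n <- build_network(cm, threshold = cfg$network$threshold, sectors = sectors)
    n$nodes$hub <- n$nodes$degree >= cfg$network$hub_min_degree
    n
  })
  report$network <- net

  if (!is.null(cfg$structure)) {
    report$structure <- run_stage("structure", {
      model <- if (!is.null(cfg$structure$path)) {
        read_ca_structure(cfg$structure$path,
                          chain = cfg$structure$chain %||% "A",
                          offset = cfg$structure$offset %||% 0L)
      } else {
        sim_args <- utils::modifyList(
          list(n_residues = ncol(aln$mat), seed = cfg$seed),
          cfg$structure$simulate)
        do.call(simulate_structure, sim_args)
      }
      if (nrow(net$edges) > 0) {
        dh <- distance_histogram(net, model)
        list(model = model, histogram = dh)
      } else {
        list(model = model, histogram = NULL)
      }
    })
  }

  if (!is.null(cfg$kinetics)) {
    report$cycles <- run_stage("cycles", {
      tit <- cfg$kinetics$titrations
      if (is.character(tit)) tit <- utils::read.csv(tit)
      man <- cfg$kinetics$manifest
      if (is.character(man)) man <- utils::read.csv(man)
      fits <- fit_titrations(tit)
      res <- run_mutant_cycles(fits, man,
                               temperature = cfg$kinetics$temperature %||% 298,
                               additivity_bound = cfg$kinetics$additivity_bound %||% 1.0)
      res$offset <- if (nrow(res$table) >= 2) additivity_offset(res$table) else NULL
      res
    })
  }

  report$truth <- truth
  report$summary <- list(
    n_sequences = nrow(aln$mat),
    n_columns = ncol(aln$mat),
    n_network_residues = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_hubs = sum(net$nodes$hub),
    degree_range = if (nrow(net$nodes)) range(net$nodes$degree) else c(NA, NA),
    distal_fraction = report$structure$histogram$distal_fraction %||% NA_real_,
    additivity_offset = report$cycles$offset$offset %||% NA_real_
  )
  class(report) <- "kinwire_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, cfg$out_dir)
  }
  report
}

#' @export
print.kinwire_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<kinwire_report> %d x %d alignment -> %d network residues, ",
                     "%d edges, %d hubs (config %s)\n"),
              s$n_sequences, s$n_columns, s$n_network_residues, s$n_edges,
              s$n_hubs, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Writes `report.json` (machine summary with the config hash), `report.md`
#' (human summary), plus edge/node/sector tables, to `out_dir`.
#'
#' @param report A `kinwire_report` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$summary
  machine <- list(config_hash = report$config_hash, summary = s,
                  curation = report$curation,
                  sectors = report$sectors,
                  cycles = report$cycles$table)
  jsonlite::write_json(machine, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  md <- c("# kinwire pipeline report", "",
          sprintf("- config hash: `%s`", report$config_hash),
          sprintf("- alignment: %d sequences x %d columns",
                  s$n_sequences, s$n_columns),
          sprintf("- network: %d residues, %d edges, %d hubs, degree %s-%s",
                  s$n_network_residues, s$n_edges, s$n_hubs,
                  s$degree_range[1], s$degree_range[2]),
          if (!is.na(s$distal_fraction))
            sprintf("- distal fraction of coupled pairs: %.1f%%",
                    100 * s$distal_fraction),
          if (!is.na(s$additivity_offset))
            sprintf("- additivity offset: %.2f kcal/mol", s$additivity_offset))
  writeLines(md, file.path(out_dir, "report.md"))
  write_network(report$network, file.path(out_dir, "edges.tsv"),
                file.path(out_dir, "nodes.csv"))
  if (!is.null(report$sectors)) {
    utils::write.csv(report$sectors, file.path(out_dir, "sectors.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
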