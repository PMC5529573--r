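#' Pipeline configuration
#'
#' Declares one end-to-end run: either a simulate block (synthetic community
#' with known truth) or a set of input paths (counts TSV, metadata TSV, Newick
#' tree, optional profile TSVs) — exactly one of the two — plus the
#' rarefaction, diversity, envelope and Mantel settings and a single global
#' seed from which every stage derives its stream.
#'
#' @param outdir Output directory for artifacts.
#' @param seed Global integer seed.
#' @param simulate `NULL` or a list of arguments for [simulate_community()]
#'   (e.g. `n_samples`, `n_otus`, `sparsity`).
#' @param inputs `NULL` or a named list with paths `counts`, `metadata`,
#'   `tree`, and optionally `profiles` (named character vector of TSV paths).
#' @param rarefaction_depth Reads per sample after rarefaction; samples below
#'   it are dropped.
#' @param n_replicates Rarefaction replicates.
#' @param metrics Diversity metrics to compute.
#' @param envelope_variables Gradient variables for the envelope suite.
#' @param envelope An [envelope_config()].
#' @param binning A [binning_config()].
#' @param mantel_variables Environmental variables entering the Euclidean
#'   environmental distance.
#' @param n_perm Mantel permutations.
#' @param nutrient_variable Metadata column used for the scenario nutrient
#'   axis.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            simulate = list(), inputs = NULL,
                            rarefaction_depth = 800L, n_replicates = 10L,
                            metrics = c("pd", "uw_unifrac", "w_unifrac"),
                            envelope_variables = c("temperature", "depth", "salinity"),
                            envelope = envelope_config(),
                            binning = binning_config(),
                            mantel_variables = c("temperature", "salinity", "nitrate"),
                            n_perm = 999L,
                            nutrient_variable = "nitrate") {
  has_sim <- !is.null(simulate)
  has_inputs <- !is.null(inputs)
  if (has_sim == has_inputs) {
    abort("config must contain exactly one of a simulate block or input paths")
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
         inputs = inputs, rarefaction_depth = as.integer(rarefaction_depth),
         n_replicates = as.integer(n_replicates), metrics = metrics,
         envelope_variables = envelope_variables, envelope = envelope,
         binning = binning, mantel_variables = mantel_variables,
         n_perm = as.integer(n_perm), nutrient_variable = nutrient_variable),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `envelope`
#' and `binning` sub-blocks are passed to their config constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$envelope)) args$envelope <- do.call(envelope_config, y$envelope)
  if (!is.null(y$binning)) args$binning <- do.call(binning_config, y$binning)
  if (is.null(y$simulate) && is.null(y$inputs)) {
    abort("config must contain exactly one of a simulate block or input paths")
  }
  if (!is.null(y$inputs)) args$simulate <- NULL
  do.call(pipeline_config, args)
}

#' Cross-validate pipeline inputs
#'
#' Checks that every count-table sample appears in the metadata and every OTU
#' is a tip of the tree (both fatal), and reports extra metadata rows or tree
#' tips as warnings.
#'
#' @param counts Count-table tibble.
#' @param metadata Metadata tibble.
#' @param tree [ape] `phylo`.
#' @param strict Abort on fatal findings (default) instead of returning them.
#' @return Tibble of findings (`level`, `message`), invisibly when empty.
#' @export
validate_inputs <- function(counts, metadata, tree, strict = TRUE) {
  findings <- tibble::tibble(level = character(), message = character())
  add <- function(level, msg) {
    findings <<- dplyr::bind_rows(findings, tibble::tibble(level = level, message = msg))
  }
  ids <- sample_ids(counts)
  miss_meta <- setdiff(ids, metadata$sample_id)
  if (length(miss_meta) > 0) {
    add("fatal", paste0("samples missing from metadata: ", paste(miss_meta, collapse = ", ")))
  }
  extra_meta <- setdiff(metadata$sample_id, ids)
  if (length(extra_meta) > 0) {
    add("warning", paste0("metadata rows without counts: ", paste(extra_meta, collapse = ", ")))
  }
  miss_tree <- setdiff(counts$otu_id, tree$tip.label)
  if (length(miss_tree) > 0) {
    add("fatal", paste0("OTUs missing from tree: ", paste(miss_tree, collapse = ", ")))
  }
  extra_tips <- setdiff(tree$tip.label, counts$otu_id)
  if (length(extra_tips) > 0) {
    add("warning", paste0("tree tips without counts: ", paste(extra_tips, collapse = ", ")))
  }
  if (strict && any(findings$level == "fatal")) {
    abort(paste0("input validation failed:\n",
                 paste(findings$message[findings$level == "fatal"], collapse = "\n")))
  }
  if (nrow(findings) == 0) invisible(findings) else findings
}

# canonical two-layer casts for the four region/season cells, mixed to the
# stated depths (m) with a thermocline step just below
default_profiles <- function() {
  cast <- function(mld, t_mixed, s_mixed, t_deep, s_deep) {
    generate_profile(data.frame(
      depth = c(0, mld, mld + 2, 200),
      temperature = c(t_mixed, t_mixed, t_deep, t_deep - 1),
      salinity = c(s_mixed, s_mixed, s_deep, s_deep)
    ))
  }
  list(
    North_Spring = cast(84, 25, 39.5, 22.5, 40.2),
    North_Fall = cast(10, 27, 39.5, 24.0, 40.2),
    South_Spring = cast(50, 30, 37.5, 26.0, 38.5),
    South_Fall = cast(15, 32, 37.0, 27.0, 38.5)
  )
}

read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate or load inputs, validate, filter to
#' the rarefaction depth, rarefy repeatedly, average diversity metrics over
#' replicates, fit the maximum-abundance envelope suite on the
#' replicate-averaged counts, compare community and environmental distances
#' with Mantel tests, derive mixed layer depths and turbulence-by-nutrient
#' scenarios, and summarise within-scenario dissimilarity — and writes every
#' artifact plus a manifest into `config$outdir`. All randomness derives from
#' `config$seed`; rerunning an identical config reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`counts`, `metadata`,
#'   `tree`, `pd`, `unifrac`, `envelope`, `mantel`, `scenarios`,
#'   `within_group`, `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # --- stage: acquire inputs -------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    design_args <- sim_args[intersect(names(sim_args),
                                      names(formals(gradient_design)))]
    design_args$seed <- seed
    other <- sim_args[intersect(names(sim_args),
                                setdiff(names(formals(simulate_community)), "design"))]
    comm <- do.call(simulate_community, c(list(design = do.call(gradient_design, design_args)), other))
    counts <- comm$counts; metadata <- comm$metadata; tree <- comm$tree
    profiles <- default_profiles()
  } else {
    counts <- read_count_table(config$inputs$counts)
    metadata <- read_metadata(config$inputs$metadata)
    tree <- read_tree(config$inputs$tree)
    profiles <- if (!is.null(config$inputs$profiles)) {
      purrr::map(config$inputs$profiles, function(p) readr::read_tsv(p, show_col_types = FALSE))
    } else {
      default_profiles()
    }
  }
  validate_inputs(counts, metadata, tree)

  with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- stage: filter + rarefy ------------------------------------------------
  rarefied <- with_stage("rarefaction", {
    kept <- filter_min_depth(counts, config$rarefaction_depth)
    if (length(sample_ids(kept)) < 4) abort("fewer than 4 samples reach the rarefaction depth")
    rarefy_replicates(kept, config$rarefaction_depth,
                      n_replicates = config$n_replicates, seed = seed)
  })
  kept_ids <- sample_ids(rarefied[[1]])
  meta_kept <- metadata[match(kept_ids, metadata$sample_id), ]

  # replicate-averaged counts, rounded back to integers, for the envelope models
  mean_counts <- with_stage("rarefaction", {
    mats <- purrr::map(rarefied, as_count_matrix)
    m <- round(Reduce(`+`, mats) / length(mats))
    count_table(m)
  })

  # --- stage: diversity ------------------------------------------------------
  pd_tbl <- NULL; unifrac <- list()
  if ("pd" %in% config$metrics) {
    pd_tbl <- with_stage("diversity", diversity_over_replicates(rarefied, tree, "pd"))
  }
  if ("uw_unifrac" %in% config$metrics) {
    unifrac$unweighted <- with_stage("diversity",
      diversity_over_replicates(rarefied, tree, "uw_unifrac"))
  }
  if ("w_unifrac" %in% config$metrics) {
    unifrac$weighted <- with_stage("diversity",
      diversity_over_replicates(rarefied, tree, "w_unifrac"))
  }

  # --- stage: envelope models ------------------------------------------------
  suite <- with_stage("envelope", {
    run_envelope_suite(mean_counts, meta_kept,
                       variables = config$envelope_variables,
                       config = config$envelope, binning = config$binning)
  })

  # --- stage: mantel ---------------------------------------------------------
  mantel <- with_stage("mantel", {
    env_dm <- env_distance(meta_kept, config$mantel_variables)
    purrr::imap(unifrac, function(dm, which) {
      mantel_test(dm, env_dm, n_perm = config$n_perm, seed = seed)
    })
  })

  # --- stage: scenarios ------------------------------------------------------
  scen <- with_stage("scenarios", {
    mlds <- purrr::map_dbl(profiles, mixed_layer_depth)
    title_case <- function(s) paste0(toupper(substr(s, 1, 1)), substring(s, 2))
    cells <- paste(title_case(meta_kept$region), title_case(meta_kept$season), sep = "_")
    nutrient <- tapply(meta_kept[[config$nutrient_variable]], cells, mean)
    common <- intersect(names(mlds), names(nutrient))
    cls <- scenario_classify(mlds[common], as.numeric(nutrient[common]))
    cls$cell <- common
    wg <- if (length(unifrac) > 0) {
      groups <- setNames(cells, meta_kept$sample_id)
      purrr::imap_dfr(unifrac, function(dm, which) {
        dplyr::mutate(
          suppressWarnings(within_group_dissimilarity(dm, groups)),
          metric = which, .before = 1
        )
      })
    } else NULL
    list(table = cls, within_group = wg)
  })

  # --- stage: write artifacts ------------------------------------------------
  out <- function(...) file.path(config$outdir, ...)
  write_count_table(counts, out("counts.tsv"))
  readr::write_tsv(metadata, out("metadata.tsv"))
  ape::write.tree(tree, out("tree.nwk"))
  write_count_table(mean_counts, out("rarefied_mean_counts.tsv"))
  if (!is.null(pd_tbl)) readr::write_tsv(pd_tbl, out("faiths_pd.tsv"))
  write_dm <- function(dm, path) {
    readr::write_tsv(dplyr::bind_cols(tibble::tibble(sample_id = rownames(dm)),
                                      tibble::as_tibble(dm)), path)
  }
  if (!is.null(unifrac$unweighted)) write_dm(unifrac$unweighted, out("unifrac_unweighted.tsv"))
  if (!is.null(unifrac$weighted)) write_dm(unifrac$weighted, out("unifrac_weighted.tsv"))

  fits_json <- purrr::pmap(suite$fits, function(taxon, variable, status, fit) {
    rec <- list(taxon = taxon, variable = variable, status = status, seed = seed)
    if (!is.null(fit)) {
      rec <- c(rec, list(
        degree = fit$degree, coefficients = fit$coefficients,
        aic = fit$aic, deviance_explained = fit$deviance_explained,
        shape = fit$shape,
        peaks = purrr::pmap(fit$peaks, function(x, abundance, interior) {
          list(x = x, abundance = abundance, interior = interior)
        }),
        abundance_unit = fit$abundance_unit
      ))
    }
    rec
  })
  jsonlite::write_json(fits_json, out("envelope_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(tidy(suite), out("envelope_summary.tsv"))

  jsonlite::write_json(
    purrr::map(mantel, function(m) {
      list(r = m$statistic, p = m$p_value, n_perm = m$n_perm,
           method = m$method, n_samples = m$n_samples, seed = seed)
    }),
    out("mantel.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_tsv(scen$table, out("scenarios.tsv"))
  if (!is.null(scen$within_group)) readr::write_tsv(scen$within_group, out("within_group_dissimilarity.tsv"))

  manifest <- list(
    package = "maxenvelope",
    version = as.character(utils::packageVersion("maxenvelope")),
    seed = seed,
    n_samples_input = length(sample_ids(counts)),
    n_samples_kept = length(kept_ids),
    n_otus = nrow(counts),
    rarefaction_depth = config$rarefaction_depth,
    n_replicates = config$n_replicates,
    metrics = config$metrics,
    envelope_variables = config$envelope_variables,
    abundance_unit = config$envelope$abundance_unit,
    mantel_variables = config$mantel_variables,
    n_perm = config$n_perm
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    counts = counts, metadata = metadata, tree = tree,
    rarefied = rarefied, mean_counts = mean_counts,
    pd = pd_tbl, unifrac = unifrac, envelope = suite, mantel = mantel,
    scenarios = scen$table, within_group = scen$within_group,
    outdir = config$outdir
  ))
}
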