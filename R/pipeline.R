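# Whole-pipeline orchestration -------------------------------------------

#' Run the full morphological-diversification pipeline
#'
#' Executes distances -> ordination -> morphospace -> disparity ->
#' (timescale) -> rates -> statistics from a single declarative
#' configuration, writing CSV/JSON/Newick artifacts and a manifest to an
#' output directory. Any stage failure aborts with the stage name.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognised fields: `seed`; `outdir`; `simulate` (a list passed to
#'   [simulate_study()], used when no input files are given); `matrix`,
#'   `dialect`, `tree`, `ranges` (input file paths); `groups` (named list
#'   of taxon vectors); `n_axes` (default 20); `nperm_mantel` (999),
#'   `nperm_group` (9999); `nsim_envelope` (999); `n_bootstrap` (1000);
#'   `optimization` ("acctran"); `calibration` (list with `method`,
#'   `mbl`, `root_buffer`, used when the supplied tree has no branch
#'   lengths).
#' @return Invisibly, a list with every stage's result plus the summary
#'   written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  seed <- cfg$seed %||% 1L
  outdir <- cfg$outdir %||% stop("config needs an `outdir`", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # inputs ----
  dat <- stage("inputs", {
    if (!is.null(cfg$matrix)) {
      m <- read_character_matrix(cfg$matrix, dialect = cfg$dialect %||% "nexus")
      tree <- if (!is.null(cfg$tree)) read_tree(cfg$tree, taxa = m) else NULL
      ranges <- if (!is.null(cfg$ranges)) read_ranges(cfg$ranges) else NULL
      groups <- cfg$groups
      bins <- if (!is.null(cfg$bins)) do.call(time_bins, cfg$bins)
              else cynodont_bins()
      list(matrix = m, tree = tree, ranges = ranges, groups = groups,
           bins = bins)
    } else {
      sim <- do.call(simulate_study,
                     c(cfg$simulate %||% list(), list(seed = seed)))
      write_character_matrix(sim$matrix, file.path(outdir, "matrix.nex"))
      utils::write.csv(sim$ranges, file.path(outdir, "ranges.csv"),
                       row.names = FALSE)
      sim$groups <- split(names(sim$groups), as.character(sim$groups))
      sim
    }
  })

  # timescale ----
  tree <- stage("timescale", {
    if (is.null(dat$tree)) stop("no tree available")
    if (is.null(dat$tree$edge.length) && !is.null(dat$ranges)) {
      cal <- dat$tree <- calibrate_tree(
        dat$tree, dat$ranges,
        method = cfg$calibration$method %||% "mbl",
        mbl = cfg$calibration$mbl %||% 1,
        root_buffer = cfg$calibration$root_buffer %||% 2)
      ape::write.tree(cal, file.path(outdir, "dated_tree.nwk"))
      cal
    } else dat$tree
  })

  # distances ----
  ged <- stage("distances", {
    d <- ged_matrix(dat$matrix)
    write_distances(d, file.path(outdir, "ged.csv"))
    d
  })
  phy_d <- stage("distances", patristic_distances(tree, transform = "sqrt"))

  # ordination ----
  ord <- stage("ordination", {
    o <- suppressWarnings(pco(ged, n_axes = min(cfg$n_axes %||% 20,
                                                nrow(ged) - 1)))
    utils::write.csv(o$scores, file.path(outdir, "pco_scores.csv"))
    utils::write.csv(data.frame(eigenvalue = o$eigenvalues),
                     file.path(outdir, "pco_eigenvalues.csv"), row.names = FALSE)
    o
  })

  # morphospace ----
  morpho <- stage("morphospace", {
    cl <- morphospace_clustering(ord, nsim = cfg$nsim_envelope %||% 999,
                                 seed = seed_offset(seed, 11))
    utils::write.csv(data.frame(r = cl$k$r, k_obs = cl$k$k_obs,
                                k_theo = cl$k$k_theo,
                                lo = cl$envelope$lo, hi = cl$envelope$hi),
                     file.path(outdir, "k_function.csv"), row.names = FALSE)
    cl
  })

  # disparity ----
  nboot <- cfg$n_bootstrap %||% 1000
  disp_g <- stage("disparity", {
    p <- disparity_by_group(ord, dat$groups, n_reps = nboot,
                            seed = seed_offset(seed, 21))
    utils::write.csv(p, file.path(outdir, "disparity_groups.csv"),
                     row.names = FALSE)
    p
  })
  disp_t <- stage("disparity", {
    if (is.null(dat$ranges)) NULL else {
      p <- disparity_through_time(ord, dat$ranges, dat$bins, n_reps = nboot,
                                  seed = seed_offset(seed, 22))
      utils::write.csv(p, file.path(outdir, "disparity_time.csv"),
                       row.names = FALSE)
      p
    }
  })

  # rates ----
  rates <- stage("rates", {
    bc <- fitch_optimize(tree, dat$matrix,
                         optimization = cfg$optimization %||% "acctran")
    bc <- completeness_correct(bc, dat$matrix)
    bc <- suppressWarnings(branch_rates(bc))
    utils::write.csv(bc$edges, file.path(outdir, "branch_rates.csv"),
                     row.names = FALSE)
    write_rates_tree(bc, file.path(outdir, "rates_tree.nwk"))
    bc
  })
  rate_tests <- stage("rates", rate_equality_tests(rates))

  # stats ----
  stats_out <- stage("stats", {
    mt <- mantel_test(ged, phy_d[rownames(ged), rownames(ged)],
                      method = "spearman",
                      nperm = cfg$nperm_mantel %||% 999,
                      seed = seed_offset(seed, 31))
    nm <- npmanova(ord$scores, groups_to_vector(dat$groups),
                   nperm = cfg$nperm_group %||% 9999,
                   seed = seed_offset(seed, 32))
    an <- anosim_test(ged, groups_to_vector(dat$groups),
                      nperm = cfg$nperm_group %||% 9999,
                      seed = seed_offset(seed, 33))
    gr <- rates_by_group(rates, dat$groups)
    kw <- rate_group_tests(gr)
    reg <- tryCatch(
      rate_time_regression(rates_by_interval(rates, dat$bins), dat$bins),
      error = function(e) NULL)
    list(mantel = mt, npmanova = nm, anosim = an, rate_groups = kw,
         rate_regression = reg)
  })

  summary <- list(
    seed = seed,
    n_taxa = length(dat$matrix$taxon_labels),
    n_characters = dat$matrix$n_characters,
    n_retained_axes = ord$n_retained,
    clustered = morpho$clustered,
    mantel_rho = stats_out$mantel$statistic,
    mantel_p = stats_out$mantel$p,
    npmanova_F = stats_out$npmanova$statistic,
    npmanova_p = stats_out$npmanova$p,
    anosim_R = stats_out$anosim$statistic,
    anosim_p = stats_out$anosim$p,
    kruskal_H = stats_out$rate_groups$kruskal$H,
    kruskal_p = stats_out$rate_groups$kruskal$p,
    rate_lrt_statistic = rate_tests$global$statistic,
    rate_lrt_p = rate_tests$global$p,
    rate_time_slope = stats_out$rate_regression$slope %||% NA,
    rate_time_tau = stats_out$rate_regression$tau %||% NA
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package_version = as.character(utils::packageVersion("morphodiv")),
                   seed = seed, config = cfg[setdiff(names(cfg), "outdir")],
                   created = "run_pipeline")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(data = dat, tree = tree, ged = ged, ordination = ord,
                 morphospace = morpho, disparity_groups = disp_g,
                 disparity_time = disp_t, rates = rates,
                 rate_tests = rate_tests, stats = stats_out,
                 summary = summary))
}

groups_to_vector <- function(groups) {
  if (!is.list(groups)) return(groups)
  stats::setNames(rep(names(groups), lengths(groups)), unlist(groups))
}

#' Split branch rates by the group of their descendant tips
#'
#' A branch belongs to a group when all its descendant tips do; branches
#' spanning groups (e.g. the stems joining them) are left out.
#'
#' @param changes A `branch_changes` object after [branch_rates()].
#' @param groups Named list of taxon vectors or named vector by taxon.
#' @return Named list of rate vectors.
#' @export
rates_by_group <- function(changes, groups) {
  sets <- groups_as_list(groups)
  tree <- changes$tree
  ed <- changes$edges
  out <- lapply(sets, function(taxa) {
    r <- numeric(0)
    for (e in seq_len(nrow(ed))) {
      below <- tree$tip.label[tips_below(tree, ed$child[e])]
      if (all(below %in% taxa) && !ed$excluded[e] && !is.na(ed$rate[e]))
        r <- c(r, ed$rate[e])
    }
    r
  })
  names(out) <- names(sets)
  out
}
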