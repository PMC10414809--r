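#' Number of distinct k-species interaction combinations
#'
#' The parameterization burden of mechanistic approaches: the number of
#' unordered k-species subsets of an S-species pool (`k = 1` counts the
#' intraspecific terms). For a pool of 10 species this gives 10, 45, 120
#' and 210 combinations at orders 1-4, which is why associations are
#' inferred statistically rather than parameterized exhaustively.
#'
#' @param S species pool size (integer >= 1).
#' @param k interaction order, `1 <= k <= S`.
#' @return exact integer count `choose(S, k)`.
#' @examples
#' count_interaction_combinations(10, 2)  # 45
#' @export
count_interaction_combinations <- function(S, k) {
  if (length(S) != 1L || length(k) != 1L || S != round(S) || k != round(k)) {
    stop("S and k must be single integers", call. = FALSE)
  }
  if (k < 1 || k > S) {
    stop("interaction order k must satisfy 1 <= k <= S", call. = FALSE)
  }
  v <- round(choose(S, k))
  if (v <= .Machine$integer.max) as.integer(v) else v
}

#' Read a pipeline configuration file
#'
#' YAML-mapped configuration for [run_pipeline()]. Top-level keys:
#' `community` and optional `covariates` (CSV paths), `outdir`, `seed`,
#' and blocks `fit` (`method`, `penalty`), `screen` (`n_permutations`,
#' `fdr`), `network` (`min_weight`), and optional `dynamics`
#' (`beta_scale`, `alpha_scale`, `self_regulation`, `r`, `N0`, `E0`,
#' `t_max`, `dt`, `E_fixed`).
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

#' Run the end-to-end constructive-network pipeline
#'
#' Executes fit -> null-model screening -> network assembly -> (optional)
#' dynamics on a community/covariate CSV pair, writing every artifact plus
#' a JSON manifest (package version, seeds, per-stage timings and status,
#' md5 of each file). Reruns with identical configuration and seed produce
#' byte-identical CSV/TSV artifacts. With `resume = TRUE`, stages whose
#' outputs already exist are skipped.
#'
#' @param config a configuration list (see [read_pipeline_config()]) or a
#'   YAML path.
#' @param resume skip stages whose declared outputs already exist.
#' @return invisibly, the manifest list (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(!is.null(config$community), !is.null(config$outdir))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(package = "constnet",
                   version = as.character(utils::packageVersion("constnet")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = seed, config = config, stages = list(), files = list())

  stage <- function(name, outputs, run) {
    paths <- file.path(outdir, outputs)
    t0 <- proc.time()[["elapsed"]]
    status <- if (resume && all(file.exists(paths))) "cached" else {
      ok <- tryCatch({ run(); TRUE },
                     error = function(e) {
                       stop("pipeline stage '", name, "' failed: ",
                            conditionMessage(e), call. = FALSE)
                     })
      "completed"
    }
    manifest$stages[[name]] <<- list(
      status = status, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = outputs)
    for (p in paths) manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
  }

  data <- read_community_csv(config$community,
                             mode = config$mode %||% "auto")
  covars <- if (!is.null(config$covariates)) read_covariate_csv(config$covariates)
  fit_cfg <- config$fit %||% list()
  method <- fit_cfg$method %||% "auto"
  penalty <- fit_cfg$penalty %||% 1e-3

  fit <- NULL
  stage("fit", c("alpha.csv", "beta.csv", "fit.json"), function() {
    fit <<- mrf_fit(data, covars, method = method, penalty = penalty)
    write_fit(fit, outdir)
  })
  if (is.null(fit)) fit <- local({  # resumed: refit in memory (cheap, not rewritten)
    suppressWarnings(mrf_fit(data, covars, method = method, penalty = penalty))
  })

  scr_cfg <- config$screen %||% list()
  n_perm <- scr_cfg$n_permutations %||% 199L
  fdr <- scr_cfg$fdr %||% 0.05
  screen_method <- if (fit$method == "exact_ml") "exact" else "pseudolikelihood"
  bscreen <- NULL; ascreen <- NULL
  do_screen <- !identical(scr_cfg$enabled %||% TRUE, FALSE) &&
    fit$method %in% c("exact_ml", "pseudolikelihood")
  if (do_screen) {
    stage("screen", c("screen_beta.csv", "screen_alpha.csv"), function() {
      bscreen <<- screen_beta(data, covars, fit_method = screen_method,
                              n_permutations = n_perm, fdr = fdr,
                              seed = seed, penalty = penalty)
      ascreen <<- screen_alpha(data, covars, fit_method = screen_method,
                               n_permutations = n_perm, fdr = fdr,
                               seed = seed + 1L, penalty = penalty)
      write_screen_csv(bscreen, file.path(outdir, "screen_beta.csv"))
      write_screen_csv(ascreen, file.path(outdir, "screen_alpha.csv"))
    })
  } else {
    manifest$stages[["screen"]] <- list(status = "skipped", seconds = 0,
                                        outputs = character(0))
  }

  net <- NULL
  stage("network", c("edges.tsv", "network.graphml"), function() {
    net <<- build_network(fit, screen = bscreen, alpha_screen = ascreen,
                          fdr = fdr,
                          min_weight = config$network$min_weight %||% 0,
                          provenance = list(seed = seed))
    write_edge_tsv(net, file.path(outdir, "edges.tsv"))
    write_network_graphml(net, file.path(outdir, "network.graphml"))
  })

  dyn_cfg <- config$dynamics
  if (!is.null(dyn_cfg)) {
    stage("dynamics", "trajectory.csv", function() {
      spec <- rescale_from_mrf(
        fit,
        beta_scale = dyn_cfg$beta_scale %||% 0.1,
        alpha_scale = dyn_cfg$alpha_scale %||% 0.1,
        self_regulation = dyn_cfg$self_regulation %||% 1.0,
        r = dyn_cfg$r, K_drive = dyn_cfg$K_drive)
      S <- length(spec$r)
      tr <- simulate_dynamics(
        spec,
        N0 = as.numeric(dyn_cfg$N0 %||% rep(0.1, S)),
        E0 = dyn_cfg$E0,
        t_max = dyn_cfg$t_max %||% 50,
        dt = dyn_cfg$dt %||% 0.01,
        record_every = as.integer(dyn_cfg$record_every %||% 10L),
        E_fixed = dyn_cfg$E_fixed)
      write_trajectory_csv(tr, file.path(outdir, "trajectory.csv"))
    })
  } else {
    manifest$stages[["dynamics"]] <- list(status = "skipped", seconds = 0,
                                          outputs = character(0))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
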