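# Config-driven orchestration of the full analysis suite over a synthetic
# or user-supplied trajectory, with a manifest for bit-reproducible reruns.

.CONFIG_KEYS <- c("input", "synth", "output_dir", "seed", "log_level",
                  "analyses")
.ANALYSIS_KEYS <- c("rdf", "first_minimum", "adf", "cdf_dist_angle",
                    "cdf_dist_dist", "sdf", "hbond", "occupancy",
                    "gaussian_fit", "energy", "stability", "msd",
                    "self_diffusion", "vacf", "vrd", "viscosity")

.validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: config must be a list or a YAML path")
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$output_dir)) stop("config error: output_dir is required")
  if (is.null(config$input) && is.null(config$synth)) {
    stop("config error: either input or synth must be given")
  }
  if (!is.null(config$analyses)) {
    bad <- setdiff(names(config$analyses), .ANALYSIS_KEYS)
    if (length(bad)) {
      stop("config error: unknown analysis block(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.pipe_log <- function(level, config, ...) {
  lv <- if (is.null(config$log_level)) "info" else config$log_level
  if (lv == "quiet") return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
}

.run_stage <- function(name, config, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("stage error in '", name, "': ", conditionMessage(e), call. = FALSE)
  })
  .pipe_log("info", config,
            sprintf("stage %-16s %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full analysis pipeline from a configuration
#'
#' Loads (or synthesizes) a trajectory and runs the configured analyses in
#' the order structure, hydrogen bonds, energetics, dynamics; every result
#' is written as CSV (or JSON for scalar reports), and a manifest records
#' parameters, package version, seed and input digests so a rerun with the
#' same config and seed is bit-identical.
#'
#' The configuration is a plain list (or YAML path) with keys: `input`
#' (list with `trajectory`, `format`, `topology`, `topology_format`,
#' optional `params`, `box`) or `synth` (list with `kind =
#' "toy_des_mixture"` and its generator arguments), `output_dir`, `seed`,
#' `log_level` (`"info"` or `"quiet"`), and `analyses`, a named list of
#' per-analysis parameter blocks (`rdf`, `first_minimum`, `adf`,
#' `cdf_dist_angle`, `cdf_dist_dist`, `sdf`, `hbond`, `occupancy`,
#' `gaussian_fit`, `energy`, `stability`, `msd`, `self_diffusion`, `vacf`,
#' `vrd`, `viscosity`). Unknown keys are rejected before any computation.
#'
#' @param config List or YAML file path.
#' @return Invisibly, the manifest list (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- .validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "destraj",
                   version = as.character(utils::packageVersion("destraj")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "output_dir")],
                   outputs = list(), inputs = list())

  # --- input stage
  if (!is.null(config$synth)) {
    traj_top <- .run_stage("synth", config, {
      sp <- config$synth
      if (!identical(sp$kind, "toy_des_mixture")) {
        stop("only synth kind 'toy_des_mixture' is supported in the pipeline")
      }
      args <- sp[setdiff(names(sp), "kind")]
      args$seed <- config$seed
      do.call(gen_toy_des_mixture, args)
    })
    traj <- traj_top$trajectory
    top <- traj_top$topology
  } else {
    traj <- .run_stage("input", config, {
      inp <- config$input
      top <- load_topology(inp$topology,
                           format = if (is.null(inp$topology_format)) "table"
                                    else inp$topology_format,
                           params = inp$params)
      manifest$inputs <- lapply(
        Filter(is.character, inp),
        function(p) if (file.exists(p)) unname(tools::md5sum(p)) else NA)
      load_trajectory(inp$trajectory,
                      format = if (is.null(inp$format)) "xyz" else inp$format,
                      topology = top, box = inp$box)
    })
    top <- traj$topology
  }

  outputs <- list()
  emit <- function(name, df, header = list()) {
    path <- file.path(config$output_dir, paste0(name, ".csv"))
    write_result_csv(df, path, c(list(analysis = name, seed = config$seed),
                                 header))
    outputs[[name]] <<- basename(path)
  }
  emit_json <- function(name, obj) {
    path <- file.path(config$output_dir, paste0(name, ".json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    outputs[[name]] <<- basename(path)
  }
  an <- config$analyses
  if (is.null(an)) an <- list()

  series <- NULL
  for (name in names(an)) {
    blk <- an[[name]]
    if (is.null(blk)) blk <- list()
    .run_stage(name, config, switch(
      name,
      rdf = {
        res <- do.call(rdf, c(list(traj = traj), blk))
        emit("rdf", data.frame(r = res$r, g = res$g, cn = res$cn),
             list(rho = res$rho, dr = res$dr))
      },
      first_minimum = {
        resr <- do.call(rdf, c(list(traj = traj), an$rdf))
        fm <- first_minimum(resr)
        emit_json("first_minimum", fm[c("found", "r_min1", "peak_r",
                                        "peak_g", "cn_at_first_min")])
      },
      adf = {
        res <- do.call(adf, c(list(traj = traj), blk))
        emit("adf", data.frame(alpha = res$alpha, density = res$density,
                               counts = res$counts))
      },
      cdf_dist_angle = {
        res <- do.call(cdf_dist_angle, c(list(traj = traj), blk))
        emit("cdf_dist_angle",
             data.frame(dist = rep(res$x, times = length(res$y)),
                        angle = rep(res$y, each = length(res$x)),
                        density = as.vector(res$density)))
      },
      cdf_dist_dist = {
        res <- do.call(cdf_dist_dist, c(list(traj = traj), blk))
        emit("cdf_dist_dist",
             data.frame(dist_a = rep(res$x, times = length(res$y)),
                        dist_b = rep(res$y, each = length(res$x)),
                        density = as.vector(res$density)))
      },
      sdf = {
        res <- do.call(sdf, c(list(traj = traj), blk))
        emit("sdf", sdf_table(res))
      },
      hbond = {
        crit <- if (!is.null(blk$preset)) {
          do.call(hbond_preset, blk[intersect(names(blk),
                                              c("name", "donor", "hydrogen",
                                                "acceptor"))            ])
        } else do.call(hbond_criterion, blk)
        series <- hbond_count_series(traj, crit)
        emit("hbond", data.frame(frame = seq_along(series$counts),
                                 count = series$counts))
      },
      occupancy = {
        if (is.null(series)) stop("occupancy requires an hbond block first")
        emit("occupancy", hbond_occupancy(series))
      },
      gaussian_fit = {
        if (is.null(series)) stop("gaussian_fit requires an hbond block first")
        fit <- fit_gaussian_counts(series)
        emit_json("gaussian_fit", fit[c("a", "mean", "sigma", "se_mean",
                                        "degenerate")])
      },
      energy = {
        res <- do.call(interaction_energy_report,
                       c(list(traj = traj), blk))
        emit("energy", res)
      },
      stability = {
        if (!is.null(blk$from_table)) {
          res <- table2_check(blk$from_table)
          emit("stability", res)
        } else {
          er <- do.call(interaction_energy_report,
                        c(list(traj = traj), blk["pairs"]))
          s <- stability_factor(er$e_total[er$pair == "salt_fas"],
                                er$e_total[er$pair == "salt_water"],
                                er$e_total[er$pair == "fas_water"])
          emit_json("stability", list(S = s))
        }
      },
      msd = {
        res <- do.call(msd, c(list(traj = traj), blk))
        emit("msd", data.frame(tau = res$tau, msd = res$msd))
      },
      self_diffusion = {
        res0 <- do.call(msd, c(list(traj = traj), an$msd))
        sd <- do.call(self_diffusion, c(list(msd_result = res0), blk))
        emit_json("self_diffusion", sd[c("found", "D", "n_points")])
      },
      vacf = {
        res <- do.call(vacf, c(list(x = traj), blk))
        emit("vacf", data.frame(t = res$t, cv = res$cv),
             list(t1 = res$t1, t2 = res$t2))
      },
      vrd = {
        res <- do.call(vrd, c(list(x = traj), blk))
        emit("vrd", data.frame(tau = res$tau, vrd = res$vrd))
      },
      viscosity = {
        stress_path <- blk$stress_csv
        st <- as.matrix(utils::read.csv(stress_path,
                                        comment.char = "#")[, c("xy", "xz", "yz")])
        res <- gk_viscosity(st, volume = blk$volume,
                            temperature = blk$temperature, dt = blk$dt,
                            stress_unit = if (is.null(blk$stress_unit))
                              "kcal_molA3" else blk$stress_unit)
        emit("viscosity", data.frame(t = res$t, acf = res$acf,
                                     eta_t = res$eta_t),
             list(eta = res$eta))
      },
      stop("unknown analysis: ", name)
    ))
  }

  manifest$outputs <- outputs
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Stability factors from a transcription of printed interaction energies
#'
#' Reads a CSV with columns `des`, `ratio`, `pair`
#' (`salt_water`/`salt_fas`/`fas_water`) and `e_total` (kcal/mol; optional
#' `e_vdw`, `e_coul`), and computes the relative stability factor S per
#' (des, ratio) composition, flagging rows whose printed total does not
#' equal the sum of its printed components.
#'
#' @param path CSV path (see `inst/extdata/table2_energies.csv` for the
#'   layout).
#' @param tol Additivity tolerance (kcal/mol); the default absorbs
#'   last-digit rounding of printed values.
#' @return data.frame with `des`, `ratio`, `S`, and `additivity_ok`.
#' @export
table2_check <- function(path, tol = 1e-3) {
  tab <- utils::read.csv(path, strip.white = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("des", "ratio", "pair", "e_total")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  has_parts <- all(c("e_vdw", "e_coul") %in% names(tab))
  out <- NULL
  for (key in unique(paste(tab$des, tab$ratio))) {
    sub <- tab[paste(tab$des, tab$ratio) == key, ]
    gete <- function(p) sub$e_total[sub$pair == p][1]
    s <- stability_factor(gete("salt_fas"), gete("salt_water"),
                          gete("fas_water"))
    add_ok <- if (has_parts) {
      all(abs(sub$e_vdw + sub$e_coul - sub$e_total) < tol)
    } else NA
    out <- rbind(out, data.frame(des = sub$des[1], ratio = sub$ratio[1],
                                 S = s, additivity_ok = add_ok,
                                 stringsAsFactors = FALSE))
  }
  out
}
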