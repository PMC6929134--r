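#' Size and field sweep of polymersome experiments
#'
#' Runs [run_field_experiment()] over the cross product of capsule sizes
#' `q_values` and field strengths `xi_values`.  Each cell writes a JSON
#' summary (and optionally an extended-XYZ snapshot of the final replica)
#' into `out_dir/q<q>_xi<xi>/`; completed cells, identified by an existing
#' summary file, are skipped so an interrupted sweep can resume.  A failing
#' cell is recorded and the sweep continues.
#'
#' @param base_params An [model_params()] object giving every non-swept
#'   parameter.
#' @param q_values Numeric vector of capsule sizes.
#' @param xi_values Numeric vector of field parameters (non-empty).
#' @param seeds Replica seeds per cell.
#' @param protocol A [run_protocol()].
#' @param out_dir Results directory, or `NULL` to keep results in memory
#'   only.
#' @param write_xyz Write a final-configuration extended XYZ per cell.
#' @param verbose Progress messages.
#' @return A list of class `mps_sweep`: `table` (data frame with one row
#'   per cell: q, xi, elongation mean/se, volume defect mean/se, chain
#'   statistics, status) and `cells` (per-cell experiment objects or error
#'   messages).
#' @export
sweep_experiment <- function(base_params, q_values, xi_values,
                             seeds = seq_len(base_params$n_replicas),
                             protocol = run_protocol(), out_dir = NULL,
                             write_xyz = FALSE, verbose = FALSE) {
  if (length(xi_values) == 0)
    stop("xi_values must be non-empty", call. = FALSE)
  if (length(q_values) == 0)
    stop("q_values must be non-empty", call. = FALSE)
  grid <- expand.grid(q = q_values, xi = xi_values)
  cells <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    q <- grid$q[i]; xi <- grid$xi[i]
    tag <- sprintf("q%g_xi%g", q, xi)
    cell_dir <- if (!is.null(out_dir)) file.path(out_dir, tag) else NULL
    sum_file <- if (!is.null(cell_dir)) file.path(cell_dir, "summary.json")
                else NULL
    if (!is.null(sum_file) && file.exists(sum_file)) {
      prev <- jsonlite::read_json(sum_file, simplifyVector = TRUE)
      rows[[i]] <- as.data.frame(prev$row)
      cells[[i]] <- "cached"
      if (verbose) message(tag, ": cached")
      next
    }
    p <- base_params
    p$q <- q
    p$xi <- xi
    res <- tryCatch({
      exp_i <- run_field_experiment(p, protocol, seeds = seeds,
                                    verbose = verbose)
      sm <- exp_i$summary
      g <- function(obs, col) sm[sm$observable == obs, col]
      row <- data.frame(
        q = q, xi = xi, n_replicas = length(seeds),
        epsilon = g("epsilon", "field_mean"),
        epsilon_se = g("epsilon", "field_se"),
        epsilon_basic = g("epsilon", "basic_mean"),
        volume_defect = g("volume_defect", "field_mean"),
        volume_defect_se = g("volume_defect", "field_se"),
        moment_projection = g("moment_projection", "field_mean"),
        mean_chain_length = g("mean_chain_length", "field_mean"),
        mean_chain_length_basic = g("mean_chain_length", "basic_mean"),
        polar_occupancy = g("polar_occupancy", "field_mean"),
        status = "ok")
      list(exp = exp_i, row = row)
    }, error = function(e) {
      list(exp = conditionMessage(e),
           row = data.frame(q = q, xi = xi, n_replicas = length(seeds),
                            epsilon = NA, epsilon_se = NA, epsilon_basic = NA,
                            volume_defect = NA, volume_defect_se = NA,
                            moment_projection = NA, mean_chain_length = NA,
                            mean_chain_length_basic = NA,
                            polar_occupancy = NA, status = "error"))
    })
    rows[[i]] <- res$row
    cells[[i]] <- res$exp
    if (!is.null(cell_dir)) {
      dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(list(row = res$row), sum_file, auto_unbox = TRUE,
                           digits = NA)
      if (write_xyz && !is.character(res$exp)) {
        st <- res$exp$replicas[[length(seeds)]]$state
        write_xyz(st, file.path(cell_dir, "final.xyz"))
      }
    }
    if (verbose && !is.character(res$exp))
      message(sprintf("%s: eps = %.4f +- %.4f", tag,
                      res$row$epsilon, res$row$epsilon_se))
  }
  out <- list(table = do.call(rbind, rows), cells = cells)
  class(out) <- "mps_sweep"
  out
}

#' @export
print.mps_sweep <- function(x, ...) {
  cat("Polymersome sweep:\n")
  print(x$table[, c("q", "xi", "epsilon", "epsilon_se", "volume_defect",
                    "status")], row.names = FALSE)
  invisible(x)
}

#' Read and write run configurations
#'
#' A configuration file is a flat YAML mapping holding [model_params()]
#' fields plus optional protocol fields (`equil_window`, `equil_tolerance`,
#' `n_steps_max`, `sample_interval`, `n_measure_steps`) and sweep fields
#' (`q_values`, `xi_values`, `seeds`).  Unknown keys are errors.
#'
#' @param path File path.
#' @return `read_config`: a list with `params` ([model_params()]),
#'   `protocol` ([run_protocol()]), `sweep` (list or NULL).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  par_keys <- setdiff(names(formals(model_params)), "...")
  proto_keys <- names(formals(run_protocol))
  sweep_keys <- c("q_values", "xi_values", "seeds")
  unknown <- setdiff(names(cfg), c(par_keys, proto_keys, sweep_keys))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(model_params, cfg[intersect(names(cfg), par_keys)])
  protocol <- do.call(run_protocol, cfg[intersect(names(cfg), proto_keys)])
  sw <- cfg[intersect(names(cfg), sweep_keys)]
  list(params = params, protocol = protocol,
       sweep = if (length(sw)) sw else NULL)
}

#' @rdname read_config
#' @param params An [model_params()] object.
#' @param protocol Optional [run_protocol()].
#' @param sweep Optional list with `q_values`, `xi_values`, `seeds`.
#' @export
write_config <- function(path, params, protocol = NULL, sweep = NULL) {
  cfg <- unclass(params)
  if (!is.null(protocol)) cfg <- c(cfg, unclass(protocol))
  if (!is.null(sweep)) cfg <- c(cfg, sweep)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export a configuration as extended XYZ
#'
#' One record per particle with a species tag (`SI` inner bead, `SO` outer
#' bead, `MNP` nanoparticle), position, and for nanoparticles the moment
#' unit vector in the `mx my mz` columns.
#'
#' @param state An `mps_state`.
#' @param path Output file.
#' @param comment Comment-line text (defaults to a parameter stamp).
#' @return The path, invisibly.
#' @export
write_xyz <- function(state, path, comment = NULL) {
  p <- state$params
  n <- state$membrane$n_beads_per_shell
  nm <- state$n_mnp
  if (is.null(comment))
    comment <- sprintf(
      paste0("Properties=species:S:1:pos:R:3:moment:R:3 q=%g lambda=%g ",
             "xi=%g phi=%g cb=%g time=%g"),
      p$q, p$lambda, state$xi, p$phi, p$cb, state$time)
  species <- c(rep("SI", n), rep("SO", n), rep("MNP", nm))
  mom <- rbind(matrix(0, 2 * n, 3), state$orientations)
  lines <- c(format(2L * n + nm),
             comment,
             sprintf("%s %.8f %.8f %.8f %.6f %.6f %.6f", species,
                     state$positions[, 1], state$positions[, 2],
                     state$positions[, 3], mom[, 1], mom[, 2], mom[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read back an extended XYZ written by `write_xyz()`
#'
#' @param path File path.
#' @return List with `species`, `positions`, `moments`, `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  species <- vapply(toks, `[[`, character(1), 1)
  num <- t(vapply(toks, function(t) as.numeric(t[2:7]), numeric(6)))
  list(species = species, positions = num[, 1:3, drop = FALSE],
       moments = num[, 4:6, drop = FALSE], comment = lines[2])
}
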