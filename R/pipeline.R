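# Config-driven orchestration: validate a YAML analysis configuration
# against the trajectory topology (fail-fast), run every analysis stage in
# dependency order, and write a CSV report bundle plus a JSON manifest.
# Stage failures abort dependents but leave independent stages running.

.default_config <- function() {
  list(
    dt_ns = 1, t0_ns = 0, equilibration_ns = 0, seed = 1,
    fit_selection = "atoms=backbone",
    cluster = list(cutoff = 1.5, min_dwell_ns = 100,
                   selection = "atoms=backbone"),
    contacts = list(cutoff = 5.0, persistence_threshold = 0.8,
                    reference_frame = 1),
    interface = list(probe = 1.4, slice_dz = 0.1, r_min = 1.0, r_max = 5.0,
                     grid = 0.5, stride = 10),
    helix_pairs = list(),
    monitors = list()
  )
}

#' Standard adenylyl-cyclase helix-pair selections
#'
#' The residue ranges that remain stably helical in the AC5 catalytic core:
#' the C1 groove pair (408-420 vs 468-475) and the C2 groove pair (910-918
#' vs 978-988), on author numbering. Supply the catalytic-core chain id(s).
#'
#' @param chains chain id(s) carrying the catalytic core (default "all").
#' @return named list of helix pairs usable as \code{config$helix_pairs}.
#' @export
default_helix_pairs <- function(chains = "all") {
  ch <- if (identical(chains, "all")) "all" else paste(chains, collapse = ",")
  list(
    c1 = list(a = sprintf("chain=%s; resid=408-420", ch),
              b = sprintf("chain=%s; resid=468-475", ch)),
    c2 = list(a = sprintf("chain=%s; resid=910-918", ch),
              b = sprintf("chain=%s; resid=978-988", ch))
  )
}

.merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(user[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read an analysis configuration
#'
#' Loads a YAML configuration file and injects defaults: cluster cutoff
#' 1.5 Angstrom on backbone atoms with a 100 ns dwell filter, 5 Angstrom
#' heavy-atom contact cutoff, 0.8 persistence threshold, probe 1.4, and the
#' standard adenylyl-cyclase helix ranges (C1 408-420/468-475,
#' C2 910-918/978-988).
#'
#' @param path YAML file, or a named list already in memory.
#' @return list of class \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- .merge_config(.default_config(), user)
  class(cfg) <- "analysis_config"
  cfg
}

#' Validate an analysis configuration against a topology
#'
#' Resolves every configured selection and monitor on the topology before
#' any computation starts; all failures are aggregated into one error.
#' Also computes the number of equilibration frames to skip,
#' floor(equilibration_ns / dt_ns).
#'
#' @param config an \code{analysis_config} (or list / YAML path).
#' @param topology an \code{md_structure}.
#' @return the validated config with \code{equilibration_frames} filled in.
#' @export
validate_config <- function(config, topology) {
  if (!inherits(config, "analysis_config"))
    config <- read_analysis_config(config)
  errs <- character(0)
  check_sel <- function(label, sel) {
    tryCatch({ resolve_selection(topology, sel); NULL },
             error = function(e) sprintf("%s: %s", label,
                                         conditionMessage(e)))
  }
  add <- function(e) if (!is.null(e)) errs[[length(errs) + 1]] <<- e
  add(check_sel("fit_selection", config$fit_selection))
  add(check_sel("cluster$selection", config$cluster$selection))
  for (dom in names(config$domains %||% list()))
    add(check_sel(paste0("domains$", dom), config$domains[[dom]]))
  for (h in names(config$helix_pairs %||% list())) {
    add(check_sel(paste0("helix_pairs$", h, "$a"), config$helix_pairs[[h]]$a))
    add(check_sel(paste0("helix_pairs$", h, "$b"), config$helix_pairs[[h]]$b))
  }
  if (!is.null(config$chains_a) && !is.null(config$chains_b)) {
    for (side in c("chains_a", "chains_b")) {
      ch <- config[[side]]
      missing <- setdiff(ch, unique(topology$atoms$chain))
      if (length(missing) > 0)
        add(sprintf("%s: chain(s) %s not in topology", side,
                    paste(missing, collapse = ",")))
    }
  }
  for (m in config$monitors) {
    e <- tryCatch({
      spec <- if (is.character(m)) parse_monitor(m) else m
      .resolve_monitor_atom(topology, spec$a, spec$label)
      .resolve_monitor_atom(topology, spec$b, spec$label)
      NULL
    }, error = function(e) conditionMessage(e))
    add(e)
  }
  if (!is.null(config$equilibration_ns) && config$dt_ns > 0) {
    config$equilibration_frames <-
      floor(config$equilibration_ns / config$dt_ns)
  } else config$equilibration_frames <- 0L
  if (length(errs) > 0)
    stop("invalid analysis configuration:\n  - ",
         paste(unlist(errs), collapse = "\n  - "))
  config$validated <- TRUE
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_table <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full trajectory analysis described by a configuration
#'
#' Executes, in dependency order: trajectory loading, equilibration
#' skipping, iterative average structure, RMSD series, RMSF profile, GROMOS
#' clustering, helix-pair series, conserved-contact and persistence
#' statistics, per-stride interface reports, and distance monitors. Each
#' stage's table is written to \code{output_dir} as CSV as soon as it
#' completes; a failing stage is logged and skipped without aborting
#' independent stages. A JSON manifest (config echo, package version, seed)
#' makes the run reproducible.
#'
#' @param config an \code{analysis_config}, list, or YAML path.
#' @param trajectory optionally, an \code{md_trajectory} already in memory
#'   (otherwise read from \code{config$trajectory}).
#' @param output_dir output directory; defaults to \code{config$output_dir}.
#' @return list of class \code{report_bundle}: the tables, stage status,
#'   and output paths.
#' @export
run_analysis <- function(config, trajectory = NULL, output_dir = NULL) {
  if (!inherits(config, "analysis_config"))
    config <- read_analysis_config(config)
  if (is.null(trajectory)) {
    if (is.null(config$trajectory)) stop("config names no trajectory")
    trajectory <- read_trajectory(config$trajectory, config$dt_ns,
                                  config$t0_ns)
  }
  config <- validate_config(config, trajectory$topology)  # fail-fast
  output_dir <- output_dir %||% config$output_dir %||%
    stop("no output directory configured")

  skip <- config$equilibration_frames
  if (skip >= n_frames(trajectory))
    stop("equilibration skips all ", n_frames(trajectory), " frames")
  if (skip > 0) {
    trajectory <- md_trajectory(trajectory$topology,
                                trajectory$frames[-seq_len(skip)],
                                trajectory$dt_ns,
                                trajectory$t0_ns + skip * trajectory$dt_ns)
  }
  set.seed(config$seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  bundle <- list(tables = list(), status = list(), paths = list(),
                 output_dir = output_dir)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      bundle$status[[name]] <<- paste("failed:", conditionMessage(res))
      message(sprintf("[%s] failed: %s", name, conditionMessage(res)))
      NULL
    } else {
      bundle$status[[name]] <<- "ok"
      res
    }
  }
  fit_sel <- parse_selection(config$fit_selection)
  nf <- n_frames(trajectory)

  avg <- stage("average_structure", average_structure(trajectory, fit_sel))

  rmsd_tab <- stage("rmsd", {
    if (is.null(avg)) stop("average structure unavailable")
    tab <- rmsd_series(trajectory, fit_sel, reference = avg)
    names(tab)[2] <- "rmsd_global"
    for (dom in names(config$domains %||% list())) {
      dsel <- parse_selection(config$domains[[dom]])
      bsel <- atom_selection(chains = dsel$chains, resid = dsel$resid,
                             atoms = "backbone")
      tab[[paste0("rmsd_", dom)]] <-
        rmsd_series(trajectory, bsel, reference = avg)$rmsd
    }
    tab
  })
  if (!is.null(rmsd_tab)) {
    bundle$tables$rmsd <- rmsd_tab
    bundle$paths$rmsd <- .write_table(rmsd_tab, output_dir, "rmsd")
  }

  if (nf >= 2) {
    rmsf <- stage("rmsf", rmsf_profile(trajectory, fit_sel))
    if (!is.null(rmsf)) {
      bundle$tables$rmsf <- as.data.frame(rmsf)
      bundle$paths$rmsf <- .write_table(bundle$tables$rmsf, output_dir, "rmsf")
    }
  } else bundle$status$rmsf <- "skipped: single frame"

  if (nf >= 2) {
    cl <- stage("cluster", {
      m <- pairwise_rmsd(trajectory, parse_selection(config$cluster$selection))
      gromos_cluster(m, config$cluster$cutoff, trajectory$dt_ns,
                     config$cluster$min_dwell_ns)
    })
    if (!is.null(cl)) {
      bundle$tables$cluster_frames <-
        as.data.frame(cl, t0_ns = trajectory$t0_ns)
      bundle$tables$cluster_summary <- summary(cl)
      bundle$paths$cluster_frames <-
        .write_table(bundle$tables$cluster_frames, output_dir,
                     "cluster_frames")
      bundle$paths$cluster_summary <-
        .write_table(bundle$tables$cluster_summary, output_dir,
                     "cluster_summary")
    }
  } else bundle$status$cluster <- "skipped: single frame"

  for (dom in names(config$helix_pairs %||% list())) {
    hd <- config$helix_pairs[[dom]]
    tab <- stage(paste0("helix_", dom),
                 helix_pair_series(trajectory, hd$a, hd$b))
    if (!is.null(tab)) {
      nm <- paste0("helix_", dom)
      bundle$tables[[nm]] <- tab
      bundle$paths[[nm]] <- .write_table(tab, output_dir, nm)
    }
  }

  if (!is.null(config$chains_a) && !is.null(config$chains_b)) {
    cons <- stage("conserved_contacts",
                  conserved_contact_series(trajectory, config$chains_a,
                                           config$chains_b,
                                           config$contacts$cutoff,
                                           config$contacts$reference_frame))
    if (!is.null(cons)) {
      bundle$tables$conserved_contacts <- cons
      bundle$paths$conserved_contacts <-
        .write_table(cons, output_dir, "conserved_contacts")
    }
    pers <- stage("persistence",
                  persistence_table(trajectory, config$chains_a,
                                    config$chains_b,
                                    config$contacts$cutoff,
                                    config$contacts$persistence_threshold))
    if (!is.null(pers)) {
      bundle$tables$persistence_pairs <- pers$pairs
      bundle$tables$persistence_residues <- pers$residues
      bundle$paths$persistence_pairs <-
        .write_table(pers$pairs, output_dir, "persistence_pairs")
      bundle$paths$persistence_residues <-
        .write_table(pers$residues, output_dir, "persistence_residues")
    }
    iface <- stage("interface", {
      frames <- seq(1, nf, by = config$interface$stride)
      rows <- lapply(frames, function(i) {
        r <- interface_report(frame_structure(trajectory, i),
                              config$chains_a, config$chains_b,
                              probe = config$interface$probe,
                              slice_dz = config$interface$slice_dz,
                              r_min = config$interface$r_min,
                              r_max = config$interface$r_max,
                              grid = config$interface$grid)
        cbind(data.frame(frame = i,
                         time_ns = frame_times(trajectory)[i]),
              as.data.frame(r))
      })
      do.call(rbind, rows)
    })
    if (!is.null(iface)) {
      bundle$tables$interface <- iface
      bundle$paths$interface <- .write_table(iface, output_dir, "interface")
    }
  } else {
    bundle$status$contacts <- "skipped: no chain partition configured"
  }

  if (length(config$monitors) > 0) {
    mon <- stage("monitors", distance_series(trajectory, config$monitors))
    if (!is.null(mon)) {
      bundle$tables$monitors <- mon
      bundle$paths$monitors <- .write_table(mon, output_dir, "monitors")
    }
  }

  manifest <- list(
    package = "trajmd",
    version = as.character(utils::packageVersion("trajmd")),
    seed = config$seed,
    n_frames = nf,
    dt_ns = trajectory$dt_ns,
    t0_ns = trajectory$t0_ns,
    equilibration_frames_skipped = skip,
    status = bundle$status,
    config = unclass(config)
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  bundle$paths$manifest <- manifest_path
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle:", x$output_dir, "\n")
  for (n in names(x$status)) cat(sprintf("  %-22s %s\n", n, x$status[[n]]))
  invisible(x)
}

.load_bundle <- function(x) {
  if (inherits(x, "report_bundle")) return(x)
  if (!dir.exists(x)) stop("no such bundle directory: ", x)
  files <- list.files(x, pattern = "\\.csv$", full.names = TRUE)
  tabs <- lapply(files, utils::read.csv)
  names(tabs) <- sub("\\.csv$", "", basename(files))
  structure(list(tables = tabs, output_dir = x, status = list(),
                 paths = as.list(files)),
            class = "report_bundle")
}

#' Compare two analysis runs
#'
#' Between-system deltas of the summary observables: mean shifts of the
#' helix angles and centre distances, mean gap-index / Delta-ASA shifts,
#' the RMSF difference profile, and changes in residue persistence.
#' Positive values mean run \code{a} exceeds run \code{b}.
#'
#' @param a,b \code{report_bundle} objects or bundle directories.
#' @return list of class \code{run_comparison} of per-observable delta
#'   tables.
#' @export
compare_runs <- function(a, b) {
  a <- .load_bundle(a); b <- .load_bundle(b)
  out <- list()
  helix_names <- intersect(grep("^helix_", names(a$tables), value = TRUE),
                           grep("^helix_", names(b$tables), value = TRUE))
  if (length(helix_names) > 0) {
    out$helix <- do.call(rbind, lapply(helix_names, function(nm) {
      data.frame(pair = sub("^helix_", "", nm),
                 d_angle_deg = mean(a$tables[[nm]]$angle_deg) -
                   mean(b$tables[[nm]]$angle_deg),
                 d_distance = mean(a$tables[[nm]]$distance) -
                   mean(b$tables[[nm]]$distance))
    }))
  }
  if (!is.null(a$tables$interface) && !is.null(b$tables$interface)) {
    gi_a <- a$tables$interface$gap_index
    gi_b <- b$tables$interface$gap_index
    out$interface <- data.frame(
      d_gap_index = mean(gi_a, na.rm = TRUE) - mean(gi_b, na.rm = TRUE),
      d_delta_asa = mean(a$tables$interface$delta_asa) -
        mean(b$tables$interface$delta_asa),
      d_gap_volume = mean(a$tables$interface$gap_volume) -
        mean(b$tables$interface$gap_volume))
  }
  if (!is.null(a$tables$rmsf) && !is.null(b$tables$rmsf)) {
    pa <- a$tables$rmsf; pb <- b$tables$rmsf
    class(pa) <- class(pb) <- c("residue_profile", "data.frame")
    out$rmsf <- as.data.frame(profile_difference(pa, pb))
  }
  if (!is.null(a$tables$persistence_residues) &&
      !is.null(b$tables$persistence_residues)) {
    pa <- a$tables$persistence_residues
    pb <- b$tables$persistence_residues
    key_a <- paste(pa$side, pa$chain, pa$resno)
    key_b <- paste(pb$side, pb$chain, pb$resno)
    keys <- union(key_a, key_b)
    out$persistence <- data.frame(
      key = keys,
      fraction_a = ifelse(keys %in% key_a,
                          pa$fraction[match(keys, key_a)], 0),
      fraction_b = ifelse(keys %in% key_b,
                          pb$fraction[match(keys, key_b)], 0))
    out$persistence$d_fraction <-
      out$persistence$fraction_a - out$persistence$fraction_b
  }
  if (!is.null(a$tables$rmsd) && !is.null(b$tables$rmsd)) {
    common <- intersect(names(a$tables$rmsd), names(b$tables$rmsd))
    common <- setdiff(common, c("time_ns"))
    out$rmsd <- data.frame(
      series = common,
      d_mean = vapply(common, function(nm)
        mean(a$tables$rmsd[[nm]]) - mean(b$tables$rmsd[[nm]]), numeric(1)))
  }
  class(out) <- "run_comparison"
  out
}

#' @export
print.run_comparison <- function(x, ...) {
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(utils::head(as.data.frame(x[[nm]]), 10))
  }
  invisible(x)
}
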