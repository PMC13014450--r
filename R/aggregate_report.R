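# Replica pooling, Tukey boxplot summaries and percent-change arithmetic.
# Statistics pool frames across replicas (a triplicate of 10,001-frame
# trajectories yields 30,003 values), the convention behind the per-
# temperature summary tables.

#' Pool descriptor series across replicas
#'
#' Concatenates per-replica series of the same descriptor, preserving
#' replica provenance.
#'
#' @param series_list List of `DescriptorSeries` of identical `name`.
#' @return Data frame with columns `replica`, `time_ps`, `value`; attributes
#'   `name` and `units`.
#' @export
pool_replicas <- function(series_list) {
  if (!length(series_list)) stop("need at least one series")
  stopifnot(all(vapply(series_list, inherits, logical(1), "DescriptorSeries")))
  nm <- unique(vapply(series_list, `[[`, character(1), "name"))
  if (length(nm) != 1L) {
    stop("cannot pool different descriptors: ", paste(nm, collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(replica = i, time_ps = s$times, value = s$values)
  }))
  attr(out, "name") <- nm
  attr(out, "units") <- series_list[[1]]$units
  out
}

#' Tukey boxplot summary of a value vector
#'
#' Quartiles by linear interpolation of order statistics (R quantile type 7);
#' whiskers at the most extreme observation within 1.5 IQR of the quartiles;
#' outliers are the points beyond the whiskers. Skew direction follows the
#' mean-versus-median criterion (symmetric within a 1e-9 band).
#'
#' @param x Numeric vector, length >= 1.
#' @return List of class `SummaryStats` with fields `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `iqr`, `whisker_low`, `whisker_high`,
#'   `n_outliers`, `skew_direction`.
#' @export
summary_stats <- function(x) {
  x <- as.numeric(x)
  if (!length(x) || anyNA(x)) stop("input must be non-empty and free of NA")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  wl <- min(inside); wh <- max(inside)
  m <- mean(x); md <- q[2]
  skew <- if (abs(m - md) <= 1e-9) "symmetric" else if (m > md) "right" else "left"
  structure(list(
    n = length(x), mean = m, sd = if (length(x) > 1) stats::sd(x) else 0,
    median = md, q1 = q[1], q3 = q[3], iqr = iqr,
    whisker_low = wl, whisker_high = wh,
    n_outliers = sum(x < wl | x > wh), skew_direction = skew
  ), class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("<SummaryStats> n=%d mean=%.4g sd=%.4g median=%.4g IQR=[%.4g, %.4g] outliers=%d skew=%s\n",
              x$n, x$mean, x$sd, x$median, x$q1, x$q3, x$n_outliers,
              x$skew_direction))
  invisible(x)
}

#' @export
as.data.frame.SummaryStats <- function(x, ...) {
  data.frame(n = x$n, mean = x$mean, sd = x$sd, median = x$median,
             q1 = x$q1, q3 = x$q3, iqr = x$iqr,
             whisker_low = x$whisker_low, whisker_high = x$whisker_high,
             n_outliers = x$n_outliers, skew_direction = x$skew_direction)
}

#' Percent excess of one mean over a reference
#'
#' `100 * (other - reference) / reference`: how much larger (signed) the
#' second value is relative to the first.
#'
#' @param reference_mean,other_mean Scalar means; `reference_mean != 0`.
#' @return Signed percent.
#' @export
percent_excess <- function(reference_mean, other_mean) {
  if (any(reference_mean == 0)) stop("reference mean must be nonzero")
  100 * (other_mean - reference_mean) / reference_mean
}

#' Percent decrease from an initial to a final mean
#'
#' `100 * (initial - final) / initial`.
#'
#' @param initial_mean,final_mean Scalar means; `initial_mean != 0`.
#' @return Signed percent.
#' @export
percent_decrease <- function(initial_mean, final_mean) {
  if (any(initial_mean == 0)) stop("initial mean must be nonzero")
  100 * (initial_mean - final_mean) / initial_mean
}

#' Run the full per-protein, per-temperature analysis pipeline
#'
#' For every protein and temperature in the configuration, reads the replica
#' trajectories (multi-model PDB), computes the descriptor series (RMSD, Rg,
#' Q), pooled summary statistics, secondary-structure content,
#' protein-protein hydrogen-bond counts and salt-bridge frequencies with
#' networks, and writes CSV/JSON tables plus a run log of every threshold.
#'
#' @param config Either a list or the path of a JSON file with entries:
#'   `proteins` (list of `label` + `temperatures`, each temperature a
#'   `temperature` value and `replicas` vector of PDB paths), `output_dir`,
#'   and optional `selection` (default `"ca"`), `sb_threshold` (0.30),
#'   `sb_rmax` (4.0), `hb_rmax` (3.5), `hb_theta` (30).
#' @return Invisibly, a nested list of the computed tables (the report
#'   bundle); files are written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out_dir <- config$output_dir %||% stop("config needs an output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  selection <- config$selection %||% "ca"
  sb_threshold <- config$sb_threshold %||% 0.30
  sb_rmax <- config$sb_rmax %||% 4.0
  crit <- hbond_criteria(config$hb_rmax %||% 3.5, config$hb_theta %||% 30)

  log_lines <- c(
    "thermotraj pipeline run",
    paste0("selection: ", selection),
    paste0("salt-bridge cutoff (A): ", sb_rmax),
    paste0("formation threshold: ", sb_threshold),
    paste0("hydrogen-bond cutoffs: r <= ", crit$r_max, " A, theta <= ",
           crit$theta_max, " deg (angle at ", crit$angle_at, ")"),
    "Q switching: beta = 5 /A, lambda = 1.8, cutoff = 4.5 A, seq sep > 3"
  )

  proteins <- config$proteins
  if (is.data.frame(proteins)) proteins <- split(proteins, seq_len(nrow(proteins)))
  bundle <- list()
  for (prot in proteins) {
    label <- prot$label
    temps <- prot$temperatures
    if (is.data.frame(temps)) temps <- split(temps, seq_len(nrow(temps)))
    sb_by_temp <- list()
    for (tcfg in temps) {
      temp <- tcfg$temperature
      paths <- unlist(tcfg$replicas)
      missing <- paths[!file.exists(paths)]
      if (length(missing)) stop("missing trajectory file: ", missing[1])
      trajs <- lapply(paths, function(p) read_pdb(p)$trajectory)
      rset <- replica_set(trajs, temp, label)

      tag <- paste0(label, "_", temp, "K")
      dsc <- list()
      for (d in c("RMSD", "Rg", "Q")) {
        series <- lapply(trajs, function(tr) {
          switch(d,
            RMSD = rmsd_series(tr, selection),
            Rg = radius_of_gyration_series(tr),
            Q = q_series(tr, native_contacts(tr)))
        })
        pooled <- pool_replicas(series)
        utils::write.csv(pooled, file.path(out_dir, paste0(tag, "_", d, ".csv")),
                         row.names = FALSE)
        dsc[[d]] <- list(pooled = pooled, stats = summary_stats(pooled$value))
      }
      stats_df <- do.call(rbind, lapply(names(dsc), function(d) {
        cbind(descriptor = d, as.data.frame(dsc[[d]]$stats))
      }))
      utils::write.csv(stats_df, file.path(out_dir, paste0(tag, "_stats.csv")),
                       row.names = FALSE)

      ss <- do.call(rbind, lapply(seq_along(trajs), function(i) {
        cbind(replica = i, ss_content_series(trajs[[i]]))
      }))
      utils::write.csv(ss, file.path(out_dir, paste0(tag, "_ss.csv")),
                       row.names = FALSE)

      hb <- do.call(rbind, lapply(seq_along(trajs), function(i) {
        cbind(replica = i, hbond_series(trajs[[i]], "pp", crit))
      }))
      utils::write.csv(hb, file.path(out_dir, paste0(tag, "_hbpp.csv")),
                       row.names = FALSE)

      sb <- salt_bridge_frequencies(rset, sb_rmax)
      sb_flat <- sb[, setdiff(names(sb), "f_per_replica"), drop = FALSE]
      utils::write.csv(sb_flat, file.path(out_dir, paste0(tag, "_saltbridges.csv")),
                       row.names = FALSE)
      formed <- formed_pairs(sb, sb_threshold)
      nets <- build_networks(formed)
      jsonlite::write_json(
        lapply(nets, function(n) list(motif = n$motif, members = n$members)),
        file.path(out_dir, paste0(tag, "_networks.json")), auto_unbox = TRUE)

      sb_by_temp[[as.character(temp)]] <- sb
      bundle[[label]][[as.character(temp)]] <- list(
        descriptors = dsc, ss = ss, hb = hb, salt_bridges = sb,
        networks = nets)
      log_lines <- c(log_lines, paste0("analyzed ", tag, ": ",
                                       length(trajs), " replica(s)"))
    }
    # cross-temperature comparison on pooled means
    temps_num <- as.numeric(names(sb_by_temp))
    if (length(temps_num) > 1L) {
      t0 <- min(temps_num)
      cmp <- do.call(rbind, lapply(setdiff(temps_num, t0), function(tt) {
        do.call(rbind, lapply(c("RMSD", "Rg", "Q"), function(d) {
          m0 <- bundle[[label]][[as.character(t0)]]$descriptors[[d]]$stats$mean
          m1 <- bundle[[label]][[as.character(tt)]]$descriptors[[d]]$stats$mean
          data.frame(protein = label, descriptor = d, from_K = t0, to_K = tt,
                     difference = m1 - m0,
                     percent_change = round(percent_excess(m0, m1), 1))
        }))
      }))
      utils::write.csv(cmp, file.path(out_dir, paste0(label, "_comparison.csv")),
                       row.names = FALSE)
      bundle[[label]]$comparison <- cmp
    }
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(bundle)
}
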