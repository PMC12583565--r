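#' Call differentially methylated regions from a DMP table
#'
#' Transparent run-based caller: probes significant at
#' `q <= probe_q_max` seed candidate regions, which extend along the
#' genome while the gap to the next significant probe is at most `maxgap`
#' bp and the effect direction stays constant; runs with at least
#' `min_probes` members are emitted. Member one-sided z-scores
#' (direction-aligned, so mixed-direction regions are impossible by
#' construction) are combined by Stouffer's method with equal weights;
#' region p-values are BH-adjusted across the emitted candidates. Region
#' bounds are 0-based half-open `[first probe pos, last probe pos + 1)`.
#' Input row order is immaterial.
#'
#' @param dmp_table [moderated_t_test()] output.
#' @param manifest [probe_manifest()] covering every probe in the table.
#' @param maxgap Maximum intra-region gap between consecutive significant
#'   probes, bp (default 1000).
#' @param min_probes Minimum probes per region (default 3).
#' @param probe_q_max Per-probe significance threshold (default 0.05).
#' @return Data frame of regions: `chrom`, `start`, `end`, `n_probes`,
#'   `mean_delta_beta`, `direction`, `combined_z`, `region_p`, `region_q`,
#'   `probe_ids` (comma-joined).
#' @export
call_dmrs <- function(dmp_table, manifest, maxgap = 1000L, min_probes = 3L,
                      probe_q_max = 0.05) {
  stopifnot(maxgap > 0, min_probes >= 1, probe_q_max > 0)
  idx <- match(dmp_table$probe_id, manifest$probes$probe_id)
  if (anyNA(idx))
    stop("manifest is missing probe(s): ",
         paste(dmp_table$probe_id[is.na(idx)][1:min(3, sum(is.na(idx)))],
               collapse = ", "))
  d <- data.frame(dmp_table,
                  chrom = manifest$probes$chrom[idx],
                  pos = manifest$probes$pos[idx],
                  stringsAsFactors = FALSE)
  d <- d[d$q_value <= probe_q_max, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      mean_delta_beta = numeric(0), direction = character(0),
                      combined_z = numeric(0), region_p = numeric(0),
                      region_q = numeric(0), probe_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(empty)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]

  new_run <- c(TRUE, d$chrom[-1L] != d$chrom[-nrow(d)] |
                 diff(d$pos) > maxgap |
                 d$direction[-1L] != d$direction[-nrow(d)])
  run_id <- cumsum(new_run)
  keep_runs <- names(which(table(run_id) >= min_probes))
  if (length(keep_runs) == 0L) return(empty)

  regions <- lapply(keep_runs, function(r) {
    g <- d[run_id == as.integer(r), , drop = FALSE]
    # one-sided z from the two-sided p, aligned with the run direction
    z <- stats::qnorm(pmax(g$p_value / 2, 1e-300), lower.tail = FALSE)
    cz <- sum(z) / sqrt(length(z))
    data.frame(chrom = g$chrom[1L], start = g$pos[1L],
               end = g$pos[nrow(g)] + 1L, n_probes = nrow(g),
               mean_delta_beta = mean(g$delta_beta),
               direction = g$direction[1L], combined_z = cz,
               region_p = stats::pnorm(cz, lower.tail = FALSE),
               probe_ids = paste(g$probe_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  out$region_q <- bh_adjust(out$region_p)
  out <- out[, c("chrom", "start", "end", "n_probes", "mean_delta_beta",
                 "direction", "combined_z", "region_p", "region_q",
                 "probe_ids")]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count called regions by effect direction
#'
#' @param dmrs [call_dmrs()] output.
#' @return Named integer vector `n_total`, `n_hyper`, `n_hypo`.
#' @export
summarize_dmr_directions <- function(dmrs) {
  c(n_total = nrow(dmrs),
    n_hyper = sum(dmrs$direction == "hyper"),
    n_hypo = sum(dmrs$direction == "hypo"))
}

#' Export DMR intervals as a BED file
#' @param dmrs [call_dmrs()] output.
#' @param path Output BED (0-based half-open, name = direction, score =
#'   combined z).
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$direction,
                    round(dmrs$combined_z, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
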