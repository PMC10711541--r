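#' Thresholds for the database plausibility criteria
#'
#' @param min_density minimum genome-wide variability, in variants per
#'   1000 bp (default 1).
#' @param intergenic_min_relative minimum relative variability of intergenic
#'   regions (strictly above; default 1.0, i.e. above the genome-wide
#'   average).
#' @param splice_max_relative relative-variability cap applied to each of
#'   the four splice-site bases (strictly below; default 1.0).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_density = 1, intergenic_min_relative = 1,
                          splice_max_relative = 1) {
  if (min_density <= 0 || intergenic_min_relative <= 0 ||
      splice_max_relative <= 0)
    stop("all thresholds must be positive")
  structure(list(min_density = min_density,
                 intergenic_min_relative = intergenic_min_relative,
                 splice_max_relative = splice_max_relative),
            class = "qc_thresholds")
}

#' Audit a variant catalogue with the three plausibility criteria
#'
#' Criterion i: genome-wide variability of at least `min_density` variable
#' sites per 1000 bp. Criterion ii: relative variability of intergenic
#' regions strictly above `intergenic_min_relative`. Criterion iii:
#' depletion of variation at each of the four splice-site bases (donor +1,
#' +2; acceptor -2, -1), i.e. relative variability strictly below
#' `splice_max_relative` at all four offsets. The overall verdict is the
#' conjunction of the three. Ti/Tv (overall and coding) and the percentage
#' of coding variants are reported as context but do not gate the verdict.
#' A missing intergenic class (gene-saturated toy genomes) makes criterion
#' ii not assessable and fails it (fail-safe).
#'
#' @param catalog a `variant_catalog`.
#' @param features a `feature_catalog`.
#' @param genome the genome assembly.
#' @param introns GRanges of introns.
#' @param thresholds a [qc_thresholds()].
#' @return list of class `qc_report`: `criteria` (data.frame with measured
#'   value, threshold, pass per criterion), `verdict`, `aux` metrics.
#' @export
evaluate_database <- function(catalog, features, genome, introns,
                              thresholds = qc_thresholds()) {
  dens1000 <- 10 * genome_wide_density(catalog, genome)
  c1 <- dens1000 >= thresholds$min_density

  vt <- feature_variability(catalog, features, genome,
                            classes = c("intergenic", "coding"))
  inter_rel <- vt$relative_variability[vt$feature == "intergenic"]
  if (is.na(inter_rel)) {
    message("intergenic class absent: criterion ii not assessable, ",
            "verdict fail-safe")
    c2 <- FALSE
  } else {
    c2 <- inter_rel > thresholds$intergenic_min_relative
  }

  ssp <- splice_site_profile(catalog, introns, genome)
  four <- rbind(ssp[ssp$context == "donor" & ssp$offset %in% c("+1", "+2"), ],
                ssp[ssp$context == "acceptor" & ssp$offset %in% c("-2", "-1"), ])
  c3 <- all(four$relative_variability < thresholds$splice_max_relative)

  summ <- catalog_summary(catalog, genome, features)

  criteria <- data.frame(
    criterion = c("i_min_density", "ii_intergenic_excess",
                  "iii_splice_site_depletion"),
    measured = c(dens1000, ifelse(is.na(inter_rel), NA, inter_rel),
                 max(four$relative_variability)),
    threshold = c(thresholds$min_density, thresholds$intergenic_min_relative,
                  thresholds$splice_max_relative),
    pass = c(c1, c2, c3))

  out <- list(criteria = criteria, verdict = all(criteria$pass),
              splice_offsets = four,
              aux = list(titv = summ$titv, titv_coding = summ$titv_coding,
                         pct_coding = summ$pct_coding,
                         n_snvs = summ$n_snvs,
                         density_per_100bp = summ$density),
              thresholds = thresholds)
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Variant database plausibility audit\n")
  for (i in seq_len(nrow(x$criteria))) {
    r <- x$criteria[i, ]
    cat(sprintf("  %-26s measured %8.4f  threshold %6.3f  [%s]\n",
                r$criterion, r$measured, r$threshold,
                if (isTRUE(r$pass)) "PASS" else "FAIL"))
  }
  cat(sprintf("  context (non-gating): n = %d, Ti/Tv = %.2f, coding %.2f%% (Ti/Tv %.2f)\n",
              x$aux$n_snvs, x$aux$titv, x$aux$pct_coding, x$aux$titv_coding))
  cat("  verdict:", if (x$verdict) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @export
qc_report_json <- function(report, path) {
  jsonlite::write_json(
    list(criteria = report$criteria, verdict = report$verdict,
         aux = report$aux),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
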