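#' Plot aggregated radial profiles
#'
#' Mean +/- SD ribbon of normalized radial profiles per group, from the
#' `profiles_group.csv` table. Pure view: regenerable from the CSV alone.
#'
#' @param groupProfiles data.frame from [runActivin()] /
#'   `profiles_group.csv` (columns bin_lo, bin_hi, mean, sd, group).
#' @param file optional PNG path; when `NULL`, draws on the current device.
#' @return invisibly, `file`.
#' @export
plotRadialProfiles <- function(groupProfiles, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 720, height = 480)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  gps <- split(groupProfiles, groupProfiles$group)
  cols <- grDevices::hcl.colors(max(length(gps), 2), "Dark 3")
  mid <- (groupProfiles$bin_lo + groupProfiles$bin_hi) / 2
  graphics::plot(NA, xlim = range(mid), ylim = c(0, 1.1),
                 xlab = "distance to colony center (um)",
                 ylab = "normalized nuclear SMAD2/3 (a.u.)")
  for (i in seq_along(gps)) {
    g <- gps[[i]]
    x <- (g$bin_lo + g$bin_hi) / 2
    ok <- !is.na(g$mean)
    sdv <- ifelse(is.na(g$sd), 0, g$sd)
    graphics::polygon(c(x[ok], rev(x[ok])),
                      c((g$mean + sdv)[ok], rev((g$mean - sdv)[ok])),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(x[ok], g$mean[ok], col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = names(gps), col = cols[seq_along(gps)],
                   lwd = 2, bty = "n")
  invisible(file)
}

#' Per-colony center/edge band scatter
#'
#' @param bands data.frame from [runActivin()] / `bands.csv`.
#' @param file optional PNG path.
#' @return invisibly, `file`.
#' @export
plotBandScatter <- function(bands, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 720, height = 480)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  grp <- factor(bands$group, levels = unique(bands$group))
  x <- as.integer(grp)
  graphics::plot(NA, xlim = c(0.5, nlevels(grp) + 0.5),
                 ylim = range(c(bands$center_mean, bands$edge_mean),
                              na.rm = TRUE),
                 xaxt = "n", xlab = "", ylab = "band mean SMAD2/3 (a.u.)")
  graphics::axis(1, at = seq_len(nlevels(grp)), labels = levels(grp))
  graphics::points(x - 0.12, bands$center_mean, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.7))
  graphics::points(x + 0.12, bands$edge_mean, pch = 17,
                   col = grDevices::adjustcolor("firebrick", 0.7))
  graphics::legend("topleft", c("center band", "edge band"),
                   pch = c(16, 17), col = c("steelblue", "firebrick"),
                   bty = "n")
  invisible(file)
}

#' Per-colony marker fraction scatter
#'
#' @param domains data.frame from [runNeuruloid()] / `domains.csv`.
#' @param file optional PNG path.
#' @return invisibly, `file`.
#' @export
plotDomainFractions <- function(domains, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 720, height = 480)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  markers <- c("PAX6", "NCAD", "SOX10")
  grp <- factor(domains$group, levels = unique(domains$group))
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old), add = TRUE)
  for (m in markers) {
    v <- domains[[paste0(m, "_frac")]]
    graphics::stripchart(v ~ grp, vertical = TRUE, method = "jitter",
                         pch = 16, col = grDevices::adjustcolor("gray30", 0.6),
                         ylab = "fraction of DAPI area", main = m)
  }
  invisible(file)
}

.activinPlots <- function(out, groupProfiles, bands) {
  plotRadialProfiles(groupProfiles, file.path(out, "radial_profiles.png"))
  plotBandScatter(bands, file.path(out, "band_scatter.png"))
}

.neuruloidPlots <- function(out, domains) {
  plotDomainFractions(domains, file.path(out, "domain_fractions.png"))
}
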