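#' @export
plot.density_profile <- function(x, ...) {
  cols <- c(BB = "forestgreen", AE = "goldenrod2", LA = "steelblue",
            FP = "magenta3")
  df <- as.data.frame(x)
  mids <- (df$r_lo + df$r_hi) / 2 - attr(x, "r_s")
  m <- matrix(df$density, ncol = 4,
              dimnames = list(NULL, unique(df$phenotype)))[, PHENOTYPES]
  graphics::matplot(unique(mids), m, type = "s", lty = 1, lwd = 2,
                    col = cols, xlab = "invasion depth (um)",
                    ylab = expression(rho ~ (cells / mu * m^2)), ...)
  graphics::legend("topright", PHENOTYPES, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' @export
plot.enrichment_field <- function(x, ...) {
  df <- as.data.frame(x)
  tt <- sort(unique(df$t_h)); rr <- sort(unique(df$r_lo))
  z <- matrix(NA_real_, length(tt), length(rr))
  z[cbind(match(df$t_h, tt), match(df$r_lo, rr))] <- df$value
  graphics::image(tt, rr - attr(x, "r_s"), z, xlab = "t (h)",
                  ylab = "invasion depth (um)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  graphics::title(main = sprintf("%s enrichment (P(r,t) - P)/P",
                                 attr(x, "phenotype")))
  invisible(x)
}
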