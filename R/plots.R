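#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_raster
#'   geom_errorbar geom_hline labs scale_fill_viridis_c theme_minimal
#'   facet_wrap
NULL

# cap infinite free energies for display only
.cap_inf <- function(g, cap = NULL) {
  finite <- g[is.finite(g)]
  cap <- cap %||% (max(finite) + 2)
  ifelse(is.finite(g), g, cap)
}

#' Plot a 1D potential of mean force
#'
#' @param object A `density1d` from [project_density()].
#' @param temperature Temperature in Kelvin (default 300).
#' @param ... Unused.
#' @return A ggplot of `G(omega)`; empty bins are shown at a capped
#'   level.
#' @export
autoplot.density1d <- function(object, temperature = 300, ...) {
  pmf <- pmf_1d(object, temperature)
  ggplot(pmf, aes(x = .data$omega, y = .cap_inf(.data$free_energy))) +
    geom_line() +
    labs(
      x = bquote(omega[.(object$residue)] ~ "(deg)"),
      y = "free energy (kcal/mol)"
    ) +
    theme_minimal()
}

#' Plot a 2D free-energy surface
#'
#' @param object A `density2d` from [project_density()].
#' @param temperature Temperature in Kelvin (default 300).
#' @param ... Unused.
#' @return A ggplot heat map of the Boltzmann-inverted projection.
#' @export
autoplot.density2d <- function(object, temperature = 300, ...) {
  g <- -kT(temperature) * log(object$values)
  g <- g - min(g[is.finite(g)])
  df <- expand.grid(x = object$axis, y = object$axis)
  df$g <- .cap_inf(as.numeric(g))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$g)) +
    geom_raster() +
    scale_fill_viridis_c(name = "G (kcal/mol)") +
    labs(
      x = bquote(omega[.(object$residues[1])] ~ "(deg)"),
      y = bquote(omega[.(object$residues[2])] ~ "(deg)")
    ) +
    theme_minimal()
}

#' Plot a 3D density as a projected free-energy surface
#'
#' @param object A `density3d`.
#' @param axes Two residues to project onto (default `c(2, 7)`).
#' @param temperature Temperature in Kelvin (default 300).
#' @param ... Unused.
#' @return A ggplot heat map.
#' @export
autoplot.density3d <- function(object, axes = c(2, 7), temperature = 300,
                               ...) {
  autoplot(project_density(object, axes), temperature = temperature)
}

#' Plot a state free-energy table
#'
#' @param object An `fe_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of the relative state free energies with
#'   block-error bars where available.
#' @export
autoplot.fe_report <- function(object, ...) {
  df <- tidy(object)
  df$free_energy <- .cap_inf(df$free_energy)
  df$state <- factor(df$state, levels = df$state[order(df$free_energy)])
  p <- ggplot(df, aes(x = .data$state, y = .data$free_energy)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "G(state) - G(TTT) (kcal/mol)") +
    theme_minimal()
  if (any(is.finite(df$free_energy_sem))) {
    p <- p + geom_errorbar(
      aes(ymin = .data$free_energy - .data$free_energy_sem,
          ymax = .data$free_energy + .data$free_energy_sem),
      width = 0.3
    )
  }
  p
}

#' Plot running means of isomerization states
#'
#' @param running_mean Output of [running_mean_states()].
#' @return A ggplot of the per-residue running means with the balanced
#'   sampling level 0.5 marked.
#' @export
plot_running_mean <- function(running_mean) {
  ggplot(running_mean,
         aes(x = .data$frame, y = .data$running_mean)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    geom_line() +
    facet_wrap(~ .data$residue, ncol = 1,
               labeller = ggplot2::labeller(
                 residue = function(x) paste0("Pro", x)
               )) +
    labs(x = "frame", y = "running mean of states (trans = 1)") +
    theme_minimal()
}
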