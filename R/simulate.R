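#' Simulation configuration
#'
#' Numerical and behavioural settings of the stand simulator that are not
#' genotype parameters.
#'
#' @param layer_dz light-model layer thickness, cm.
#' @param n_sky_directions sky discretization (16 or 46), see
#'   [diffuse_sky()].
#' @param gai_radius neighbourhood radius of the surrounding-GAI perception,
#'   m.
#' @param t_base base temperature of the thermal-time clock, degC.
#' @param regression_window length of the running-mean window (days) on the
#'   per-area intercepted-PAR signal that triggers tiller regression.
#' @param regression_decay_days days over which a regressing tiller loses its
#'   green area linearly.
#' @param lperc_start_day first day after sowing entering the seasonal
#'   light-interception average `L_perc`.
#' @return named list of settings.
#' @export
sim_config <- function(layer_dz = 2, n_sky_directions = 16,
                       gai_radius = 0.15, t_base = 0,
                       regression_window = 7, regression_decay_days = 5,
                       lperc_start_day = 100) {
  list(layer_dz = layer_dz, n_sky_directions = n_sky_directions,
       gai_radius = gai_radius, t_base = t_base,
       regression_window = regression_window,
       regression_decay_days = regression_decay_days,
       lperc_start_day = lperc_start_day)
}

# status codes for axes
AX_POTENTIAL <- 0L; AX_ACTIVE <- 1L; AX_REGRESSING <- 2L; AX_REGRESSED <- 3L

#' Initialize the daily state of a stand simulation
#'
#' Draws all random quantities up front from named substreams of the master
#' seed (per-plant emergence delays, one tiller-emergence uniform per plant
#' and rank), precomputes per-plant developmental calendars, and allocates
#' the axis and leaf tables. The daily loop itself is then deterministic,
#' which is what makes seed-matched mixture / pure-stand comparisons exact.
#'
#' @param plot a [build_plot()].
#' @param climate a [generate_climate()] series covering the season.
#' @param config a [sim_config()].
#' @param seed master seed (defaults to the plot's seed).
#' @return an environment of class `stand_state`; advance it with
#'   [stand_step()].
#' @export
stand_init <- function(plot, climate, config = sim_config(),
                       seed = plot$seed) {
  n_p <- plot$n_plants
  gid <- plot$genotype_id
  gt <- plot$genotypes
  dev1 <- gt[[1]]$dev
  n_days <- nrow(climate)

  s <- new.env(parent = emptyenv())
  s$plot <- plot; s$climate <- climate; s$config <- config; s$seed <- seed
  s$tt_cum <- thermal_time(climate, config$t_base)
  s$daily_tt <- pmax(0, climate$temp_c - config$t_base)
  s$n_days <- n_days

  # per-plant genotype scalars
  pick <- function(f) vapply(gid, function(i) f(gt[[i]]), numeric(1))
  s$p_gai_c <- pick(function(g) g$gai_c)
  s$p_par_t <- pick(function(g) g$par_t)
  s$p_phyllo <- pick(function(g) g$dev$phyllochron)
  s$p_nleaf <- pick(function(g) g$dev$n_leaves_ms)
  s$p_elong0 <- pick(function(g) g$dev$elong_start)
  s$p_elong1 <- pick(function(g) g$dev$elong_end)
  s$p_flower <- pick(function(g) g$dev$flowering_tt)
  s$p_mature <- pick(function(g) g$dev$maturity_tt)
  s$p_growth <- pick(function(g) g$dev$leaf_growth_phyllo * g$dev$phyllochron)
  s$p_stemd <- pick(function(g) g$dev$stem_diameter)
  s$p_hms <- pick(function(g) g$h_ms)

  # random substreams
  s$delay <- with_seed(sub_seed(seed, "emergence_delays"),
                       stats::runif(n_p, dev1$emergence_delay_range[1],
                                    dev1$emergence_delay_range[2]))
  max_r <- dev1$max_tiller_ranks
  s$u_tiller <- with_seed(sub_seed(seed, "tiller_draws"),
                          matrix(stats::runif(n_p * max_r), n_p, max_r))
  s$max_ranks <- max_r
  s$probs <- dev1$emergence_probs

  day_at <- function(tt_target) {
    d <- findInterval(tt_target - 1e-9, s$tt_cum) + 1L
    ifelse(tt_target <= 0, 1L, d)
  }
  s$emerge_day <- day_at(s$delay)
  s$flower_day <- day_at(s$delay + s$p_flower)
  s$mature_day <- day_at(s$delay + s$p_mature)
  need <- max(s$delay + s$p_mature)
  if (max(s$tt_cum) < need)
    stop_invalid(sprintf(
      "climate too short: season accumulates %.0f degCd but maturity of the last plant needs %.0f degCd",
      max(s$tt_cum), need))
  if (min(s$flower_day) <= 45)
    stop_invalid("flowering occurs before day 46; the 45-day pre-flowering fitness window does not fit")
  s$end_day <- max(s$mature_day)

  # axis table: main stem + max_r potential tillers per plant
  n_ax <- n_p * (1L + max_r)
  s$ax_plant <- rep(seq_len(n_p), each = 1L + max_r)
  s$ax_rank <- rep(0L:max_r, times = n_p)
  s$ax_status <- ifelse(s$ax_rank == 0L, AX_ACTIVE, AX_POTENTIAL)
  s$ax_emtt <- ifelse(s$ax_rank == 0L, s$delay[s$ax_plant], NA_real_)
  s$ax_regress_day <- rep(NA_integer_, n_ax)
  s$ax_hfac <- pmax(0.5, 1 - vapply(seq_len(n_ax), function(a)
    gt[[gid[s$ax_plant[a]]]]$dev$tiller_height_drop, numeric(1)) * s$ax_rank)
  s$ax_k <- sin(pick(function(g) g$phi_b) * pi / 180)[s$ax_plant]
  s$n_axes <- n_ax

  # leaf table (grows as tillers emerge); main-stem leaves known at init
  s$lf_axis <- integer(0); s$lf_area <- numeric(0)
  s$lf_emtt <- numeric(0); s$lf_frac <- numeric(0)
  for (p in seq_len(n_p)) {
    a <- (p - 1L) * (1L + max_r) + 1L
    lt <- axis_leaf_table(gt[[gid[p]]], rank = 0, emergence_tt = s$delay[p])
    s$lf_axis <- c(s$lf_axis, rep(a, nrow(lt)))
    s$lf_area <- c(s$lf_area, lt$final_area)
    s$lf_emtt <- c(s$lf_emtt, lt$emergence_tt)
    s$lf_frac <- c(s$lf_frac, lt$pos_frac)
  }

  s$n_layers <- as.integer(ceiling(max(vapply(gt, function(g) g$h_ms,
                                              numeric(1))) / config$layer_dz))
  s$sky <- diffuse_sky(config$n_sky_directions)
  s$ground_area <- prod(plot$domain)
  d <- periodic_distances(plot)
  s$nbr <- (d <= config$gai_radius) * 1

  s$ceased <- rep(FALSE, n_p)
  s$rank_drawn <- matrix(FALSE, n_p, max_r)
  s$par_mat <- matrix(0, n_ax, n_days)
  s$ratio_mat <- matrix(NA_real_, n_ax, n_days)
  s$axis_count <- matrix(0L, n_p, n_days)
  s$interception <- rep(NA_real_, n_days)
  s$transmitted <- rep(NA_real_, n_days)
  s$day <- 0L
  class(s) <- "stand_state"
  s
}

#' Advance a stand simulation by one day
#'
#' One daily step: (a) development — leaf expansion, stem elongation,
#' senescence and the green-area decay of regressing tillers; (b) light —
#' turbid-medium partitioning of the day's incident PAR among axes;
#' (c) tiller emergence — per-rank probabilistic emission, permanently ceased
#' once the surrounding GAI reaches the genotype's `gai_c`; (d) tiller
#' regression — an active tiller whose running mean of intercepted PAR per
#' green area per degree-day falls below `par_t` regresses (main stem
#' exempt). Days must be stepped in chronological order; the state enforces
#' this.
#'
#' @param s a `stand_state` from [stand_init()].
#' @return the state, invisibly (modified in place).
#' @export
stand_step <- function(s) {
  if (!inherits(s, "stand_state")) stop_invalid("not a stand_state")
  if (s$day >= s$end_day) stop_invalid("season already complete")
  d <- s$day + 1L
  s$day <- d
  cfg <- s$config
  tt_abs <- s$tt_cum[d]
  daily <- s$daily_tt[d]
  tt_plant <- tt_abs - s$delay              # thermal age per plant

  # (a) development ----------------------------------------------------
  # regressing multiplier per axis; finish regression at 0
  mult <- rep(1, s$n_axes)
  reg <- which(s$ax_status == AX_REGRESSING)
  if (length(reg)) {
    m <- 1 - (d - s$ax_regress_day[reg]) / cfg$regression_decay_days
    done <- m <= 0
    s$ax_status[reg[done]] <- AX_REGRESSED
    mult[reg] <- pmax(0, m)
  }
  alive_ax <- s$ax_status == AX_ACTIVE | s$ax_status == AX_REGRESSING

  sen_p <- 1 - clamp((tt_plant - s$p_flower) / (s$p_mature - s$p_flower), 0, 1)
  efrac_p <- clamp((tt_plant - s$p_elong0) / (s$p_elong1 - s$p_elong0), 0, 1)
  h_ax <- s$p_hms[s$ax_plant] * s$ax_hfac * efrac_p[s$ax_plant]

  # blade areas
  lp <- s$ax_plant[s$lf_axis]
  growth <- clamp((tt_abs - s$lf_emtt) / s$p_growth[lp], 0, 1)
  bl_area <- s$lf_area * growth * sen_p[lp] * mult[s$lf_axis]
  bl_live <- bl_area > 0 & alive_ax[s$lf_axis]
  bl_layer <- pmin(floor(s$lf_frac * h_ax[s$lf_axis] / cfg$layer_dz) + 1L,
                   s$n_layers)

  # stem lateral areas, uniform along the stem
  st_ax <- which(alive_ax & h_ax > 0)
  st_i <- st_l <- integer(0); st_a <- numeric(0)
  if (length(st_ax)) {
    h <- h_ax[st_ax]
    L <- pmin(as.integer(ceiling(h / cfg$layer_dz)), s$n_layers)
    per <- pi * s$p_stemd[s$ax_plant[st_ax]] * sen_p[s$ax_plant[st_ax]] *
      mult[st_ax]
    st_i <- rep(st_ax, L)
    st_l <- sequence(L)
    full <- rep(per * cfg$layer_dz, L)
    last <- cumsum(L)
    rem <- h - (L - 1) * cfg$layer_dz
    full[last] <- per * rem
    st_a <- full
  }

  W <- matrix(0, s$n_axes, s$n_layers)
  if (length(st_i)) W[cbind(st_i, st_l)] <- st_a  # unique (axis, layer) pairs
  if (any(bl_live)) {
    # blades can collide in a layer: sort keys, aggregate by run, scatter-add
    key <- (bl_layer[bl_live] - 1L) * s$n_axes + s$lf_axis[bl_live]
    o <- order(key)
    ks <- key[o]
    cs <- cumsum(bl_area[bl_live][o])
    last <- c(ks[-1L] != ks[-length(ks)], TRUE)
    W[ks[last]] <- W[ks[last]] + diff(c(0, cs[last]))
  }
  ax_area <- rowSums(W)                     # cm2 green area per axis

  # (b) light -----------------------------------------------------------
  incident <- s$climate$par_mol_m2_d[d]
  lp_out <- partition_light(W, s$ax_k, s$sky, incident, s$ground_area)
  s$par_mat[, d] <- lp_out$intercepted
  s$transmitted[d] <- lp_out$transmitted
  s$interception[d] <- if (incident > 0)
    sum(lp_out$intercepted) / (incident * s$ground_area) else 0

  # per-axis regression signal: PAR per green area (m2) per degree-day
  ok <- ax_area > 0 & daily > 0
  s$ratio_mat[ok, d] <- lp_out$intercepted[ok] / (ax_area[ok] * 1e-4 * daily)

  # (c) tiller emergence ------------------------------------------------
  plant_area <- rowsum(ax_area, s$ax_plant)[, 1]
  emerged <- tt_plant >= 0
  cand <- which(emerged & !s$ceased)
  if (length(cand)) {
    gai <- as.numeric(s$nbr[cand, , drop = FALSE] %*% plant_area) * 1e-4 /
      (pi * cfg$gai_radius^2)
    stopnow <- gai >= s$p_gai_c[cand]
    s$ceased[cand[stopnow]] <- TRUE
    go <- cand[!stopnow]
    if (length(go)) {
      ms_leaves <- pmin(s$p_nleaf[go], floor(tt_plant[go] / s$p_phyllo[go]) + 1)
      for (j in seq_along(go)) {
        p <- go[j]
        for (r in seq_len(s$max_ranks)) {
          if (s$rank_drawn[p, r] || ms_leaves[j] < r + 3) next
          s$rank_drawn[p, r] <- TRUE
          if (s$u_tiller[p, r] < s$probs[r]) {
            a <- (p - 1L) * (1L + s$max_ranks) + 1L + r
            s$ax_status[a] <- AX_ACTIVE
            s$ax_emtt[a] <- tt_abs
            g <- s$plot$genotypes[[s$plot$genotype_id[p]]]
            lt <- axis_leaf_table(g, rank = r, emergence_tt = tt_abs)
            s$lf_axis <- c(s$lf_axis, rep(a, nrow(lt)))
            s$lf_area <- c(s$lf_area, lt$final_area)
            s$lf_emtt <- c(s$lf_emtt, lt$emergence_tt)
            s$lf_frac <- c(s$lf_frac, lt$pos_frac)
          }
        }
      }
    }
  }

  # (d) tiller regression ----------------------------------------------
  chk <- which(s$ax_status == AX_ACTIVE & s$ax_rank > 0L &
                 tt_plant[s$ax_plant] >= s$p_elong0[s$ax_plant])
  if (length(chk)) {
    w0 <- max(1L, d - s$config$regression_window + 1L)
    win <- s$ratio_mat[chk, w0:d, drop = FALSE]
    mu <- rowMeans(win, na.rm = TRUE)
    hit <- is.finite(mu) & mu < s$p_par_t[s$ax_plant[chk]]
    s$ax_status[chk[hit]] <- AX_REGRESSING
    s$ax_regress_day[chk[hit]] <- d
  }

  s$axis_count[, d] <- rowsum(
    as.integer(s$ax_status == AX_ACTIVE | s$ax_status == AX_REGRESSING),
    s$ax_plant)[, 1]
  invisible(s)
}

#' Fitness of an axis from its pre-flowering interception record
#'
#' Photothermal-quotient proxy for the grain number of one axis:
#' `F_axis = PAR_i45 / T_m45`, where `PAR_i45` is the mean daily PAR
#' intercepted by the axis over the 45 days preceding flowering
#' (mol d^-1) and `T_m45` the mean temperature over the same window (degC).
#'
#' @param par_daily intercepted PAR, mol d^-1, exactly 45 values.
#' @param temp_daily mean air temperature, degC, exactly 45 values.
#' @return `F_axis`, mol degCd^-1.
#' @examples
#' axis_fitness(rep(0.5, 45), rep(12.5, 45))  # 0.04
#' @export
axis_fitness <- function(par_daily, temp_daily) {
  if (length(par_daily) != 45L || length(temp_daily) != 45L)
    stop_invalid("fitness window must contain exactly 45 days")
  tm <- mean(temp_daily)
  if (tm <= 0)
    stop_degenerate("mean temperature over the fitness window must be positive")
  mean(par_daily) / tm
}

#' Simulate a stand from sowing to maturity
#'
#' Runs the daily loop and assembles the three stand-level outputs:
#' `n_ears` (mean surviving axes per plant at maturity; each surviving axis
#' bears one ear), `l_perc` (mean daily fraction of incident PAR intercepted
#' by the stand from `lperc_start_day` to stand maturity) and `f_tot` (sum of
#' [axis_fitness()] over surviving axes).
#'
#' @param plot a [build_plot()].
#' @param climate a [generate_climate()] series.
#' @param config a [sim_config()].
#' @param seed master seed (defaults to the plot's).
#' @return object of class `stand_outputs`: list with `n_ears`, `l_perc`,
#'   `f_tot`, `tillering_dynamics` (data.frame plant x day axis counts),
#'   `interception_dynamics` (day, fraction, transmitted) and
#'   `n_axes_per_plant`.
#' @export
simulate_stand <- function(plot, climate, config = sim_config(),
                           seed = plot$seed) {
  s <- stand_init(plot, climate, config, seed)
  while (s$day < s$end_day) stand_step(s)

  surv <- which(s$ax_status == AX_ACTIVE)
  n_per_plant <- rowsum(as.integer(s$ax_status == AX_ACTIVE), s$ax_plant)[, 1]
  fitness <- vapply(surv, function(a) {
    fd <- s$flower_day[s$ax_plant[a]]
    w <- (fd - 45L):(fd - 1L)
    axis_fitness(s$par_mat[a, w], s$climate$temp_c[w])
  }, numeric(1))

  days <- seq_len(s$end_day)
  lp_days <- days[days >= config$lperc_start_day]
  out <- list(
    n_ears = mean(n_per_plant),
    l_perc = mean(s$interception[lp_days]),
    f_tot = sum(fitness),
    n_axes_per_plant = n_per_plant,
    tillering_dynamics = data.frame(
      plant = rep(seq_len(plot$n_plants), times = s$end_day),
      day = rep(days, each = plot$n_plants),
      n_axes = as.integer(s$axis_count[, days])),
    interception_dynamics = data.frame(
      day = days, fraction = s$interception[days],
      transmitted = s$transmitted[days],
      incident = s$climate$par_mol_m2_d[days])
  )
  class(out) <- c("stand_outputs", "list")
  out
}

#' @export
print.stand_outputs <- function(x, ...) {
  cat(sprintf("<stand_outputs> n_ears=%.3f  l_perc=%.4f  f_tot=%.5f\n",
              x$n_ears, x$l_perc, x$f_tot))
  invisible(x)
}
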