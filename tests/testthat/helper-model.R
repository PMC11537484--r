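# Shared fixtures: consensus models with their default dark points, and a
# short variable-mean stimulus + forward simulation per type (memoised so
# each test file pays for it at most once).

.cell_types <- c("primate_cone", "mouse_cone", "primate_rod", "mouse_rod")

model_for <- function(cell_type, dark_current = NULL) {
  params <- consensus_params(cell_type)
  dark <- dark_operating_point(params,
                               dark_current %||% default_dark_current(cell_type))
  list(params = params, dark = dark)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_cache <- new.env(parent = emptyenv())

# Short variable-mean fixture simulation (2 s segments cones, 2 s rods,
# 3 levels) used by several inversion/clamp tests.
short_sim <- function(cell_type, seed = 7) {
  key <- paste(cell_type, seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  m <- model_for(cell_type)
  is_cone <- grepl("cone", cell_type)
  stim <- make_variable_mean_noise(
    mean_levels = if (is_cone) c(2000, 12000, 45000) else c(2, 8, 30),
    segment_dur = 2, contrast = 0.5, dt = default_dt(cell_type), seed = seed)
  init <- steady_state(m$params, m$dark, stim$values[1])
  st <- simulate_cascade(m$params, m$dark, stim,
                         initial = init[c("R", "P", "G", "C")])
  out <- list(stim = stim, st = st, params = m$params, dark = m$dark)
  .sim_cache[[key]] <- out
  out
}

# Cached linear-filter fits at the standard means (reused across clamp and
# acceptance tests).
.lfp_cache <- new.env(parent = emptyenv())

lfp_for <- function(cell_type, mean_level, seed = 11, ...) {
  extras <- list(...)
  key <- paste(cell_type, mean_level, seed,
               paste(names(extras), unlist(extras), collapse = "_"))
  if (is.null(.lfp_cache[[key]])) {
    m <- model_for(cell_type)
    .lfp_cache[[key]] <- fit_linear_model(m$params, m$dark, mean_level,
                                          seed = seed, ...)
  }
  .lfp_cache[[key]]
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
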