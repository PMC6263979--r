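# shared small fixtures for fast module tests

small_grid <- function(spacing = 2) cartesian_grid(c(40, 40, 30), spacing)

small_geom <- function(...) {
  illumination_geometry(beam_width = 6, beam_height = 1, arm_interval = 8, ...)
}

default_array <- function() linear_array()

# a steady solve on a small grid, memoised per session
small_steady_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- solve_fluence(lipofundin_1pct(), pulse_profile(),
                              small_geom(), small_grid())
    }
    cache
  }
})

# production-resolution solves shared by the acceptance criteria
production_fluence <- local({
  cache <- list()
  function(interval, angle) {
    key <- sprintf("%g_%g", interval, angle)
    if (is.null(cache[[key]])) {
      geom <- illumination_geometry(arm_interval = interval,
                                    incident_angle_deg = angle)
      cache[[key]] <<- solve_fluence(lipofundin_1pct(), pulse_profile(),
                                     geom, cartesian_grid(c(160, 80, 50), 0.5))
    }
    cache[[key]]
  }
})
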