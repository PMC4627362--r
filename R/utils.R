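# Classed conditions so callers can distinguish user error from numerics.
dwigp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dwigp_error")))
}

stop_invalid_input <- function(msg) dwigp_stop(msg, "dwigp_invalid_input")
stop_invalid_hyper <- function(msg) dwigp_stop(msg, "dwigp_invalid_hyper")
stop_conditioning  <- function(msg) dwigp_stop(msg, "dwigp_conditioning_error")
stop_format        <- function(msg) dwigp_stop(msg, "dwigp_format_error")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so library calls do not perturb user code.
# seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid_input("seed must be a single finite number or NULL")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
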