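# Phase-resolved wall-clock profiling: embedding, scoring, dynamic
# programming, total.  Timings are observational only — they never enter a
# correctness decision — and benchmark execution is serial by construction.

.new_timer <- function() {
  t <- new.env(parent = emptyenv())
  t$phases <- c(embedding = 0, scoring = 0, dp = 0)
  t$active <- NULL
  t$start <- proc.time()[["elapsed"]]
  t
}

# Time `expr` (evaluated in the caller's frame) under the named phase.
# A no-op when `timer` is NULL, so profiling cannot change results.
.phase <- function(timer, name, expr) {
  pexpr <- substitute(expr)
  if (is.null(timer)) return(invisible(eval(pexpr, parent.frame())))
  if (!is.null(timer$active)) {
    stop(sprintf("nested phase timers: '%s' started inside '%s'", name,
                 timer$active), call. = FALSE)
  }
  timer$active <- name
  t0 <- proc.time()[["elapsed"]]
  on.exit({
    timer$phases[[name]] <- timer$phases[[name]] + (proc.time()[["elapsed"]] - t0)
    timer$active <- NULL
  })
  invisible(eval(pexpr, parent.frame()))
}

.timer_close <- function(timer) {
  total <- proc.time()[["elapsed"]] - timer$start
  structure(list(embedding = unname(timer$phases[["embedding"]]),
                 scoring = unname(timer$phases[["scoring"]]),
                 dp = unname(timer$phases[["dp"]]),
                 total = total),
            class = "phase_timings")
}

#' Extract per-phase timings from a profiled alignment run
#'
#' @param x result of [progressive_align()] or [codon_align()] run with
#'   `profile = TRUE`.
#' @return A `phase_timings` object (seconds: `embedding`, `scoring`, `dp`,
#'   `total`, with `embedding + scoring + dp <= total`) or `NULL` when the
#'   run was not profiled.
#' @export
profile_phases <- function(x) attr(x, "timings", exact = TRUE)

#' @export
print.phase_timings <- function(x, ...) {
  cat(sprintf("phase timings (s): embedding %.3f | scoring %.3f | dp %.3f | total %.3f\n",
              x$embedding, x$scoring, x$dp, x$total))
  invisible(x)
}
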