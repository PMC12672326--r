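#' Health states of the cardiovascular Markov model
#'
#' The model tracks a cohort through 11 mutually exclusive health states:
#' event-free (`NoCVD`), first-year and post-year states for a first
#' myocardial infarction (`MI_y1`, `PostMI`) and for recurrent MI
#' (`MI2_y1`, `PostMI2plus`), the analogous four ischemic-stroke states
#' (`IS_y1`, `PostIS`, `IS2_y1`, `PostIS2plus`), and two absorbing death
#' states (`CVDeath`, `NonCVDeath`). The `_y1` states are tunnel states:
#' they are occupied for exactly one cycle (the first year after the event)
#' before the cohort moves on to the corresponding post-event state, unless
#' a new event or death intervenes.
#'
#' @return Character vector of the 11 state labels, in canonical order.
#' @export
health_states <- function() {
  c("NoCVD",
    "MI_y1", "PostMI", "MI2_y1", "PostMI2plus",
    "IS_y1", "PostIS", "IS2_y1", "PostIS2plus",
    "CVDeath", "NonCVDeath")
}

# Index helpers; canonical order above is relied on throughout the engine.
.state_index <- function(label) match(label, health_states())

#' @rdname health_states
#' @export
alive_states <- function() health_states()[1:9]

#' @rdname health_states
#' @export
absorbing_states <- function() c("CVDeath", "NonCVDeath")

#' @rdname health_states
#' @export
tunnel_states <- function() c("MI_y1", "MI2_y1", "IS_y1", "IS2_y1")
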