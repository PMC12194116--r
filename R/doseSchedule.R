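#' The experimental galvanic-current dose schedule
#'
#' Returns the 29 current intensities used in the dose-escalation protocol:
#' 0.10 mA increments from 0.00 to 1.00 mA, then 0.50 mA increments up to
#' the maximum intensity of 10.00 mA. One second of application per dose, so
#' dose is indexed by intensity alone.
#'
#' @return Numeric vector of 29 strictly increasing intensities in mA,
#'   from 0.00 to 10.00.
#' @examples
#' sched <- makeDoseSchedule()
#' length(sched)  # 29
#' range(sched)   # 0 .. 10
#' @export
makeDoseSchedule <- function() {
  round(c(seq(0, 1, by = 0.1), seq(1.5, 10, by = 0.5)), 2)
}
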