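#' MTR parameter sweep
#'
#' Runs paired MT-prepared and reference simulations over a grid of one
#' parameter and tabulates the signals and the resulting MTR.  The reference
#' simulation is recomputed only for axes that affect it (tissue parameters
#' and B0); for the MT-pulse axes (`delta_f`, `mt_flip`) it is computed
#' once.
#'
#' @param tissue Base [tissue_params].
#' @param prep Base [mt_preparation].
#' @param imaging An [imaging_module].
#' @param protocol A [sim_protocol].
#' @param axis One of `"delta_f"`, `"mt_flip"`, `"b0"`, `"T1_free"`,
#'   `"T2_free"`, `"exchange_rate"`, `"psr"`.
#' @param values Numeric grid for the swept parameter.  Units: Hz for
#'   `delta_f`/`b0`/`exchange_rate`, degrees for `mt_flip`, seconds for
#'   relaxation times, fraction for `psr`.
#' @return A tibble of class `mtr_sweep` with columns `value`, `signal_mt`,
#'   `signal_ref`, `mtr_percent`.
#' @examples
#' \donttest{
#' sw <- mtr_sweep(myocardium_tissue(), human_mt_prep(), spgr_module(),
#'                 sim_protocol(), "psr", c(0.05, 0.10, 0.15))
#' sw
#' }
#' @export
mtr_sweep <- function(tissue, prep, imaging, protocol, axis, values) {
  axes <- c("delta_f", "mt_flip", "b0", "T1_free", "T2_free",
            "exchange_rate", "psr")
  if (!axis %in% axes)
    stop("unknown sweep axis: ", axis)
  ref_varies <- !axis %in% c("delta_f", "mt_flip")
  at <- function(v) {
    tis <- tissue
    pr <- prep
    pro <- protocol
    if (axis %in% c("T1_free", "T2_free", "exchange_rate", "psr")) {
      tis[[axis]] <- v
      tis <- do.call(tissue_params, tis[c("T1_free", "T2_free", "psr",
                                          "exchange_rate", "T1_bound",
                                          "T2_bound")])
    } else if (axis == "b0") {
      pro$b0_offset <- v
    } else {
      p <- prep$pulse
      pr$pulse <- make_sinc_pulse(
        flip = if (axis == "mt_flip") v else p$flip,
        duration = p$duration, bandwidth = p$bandwidth, dt = p$dt,
        offset = if (axis == "delta_f") v else p$offset)
    }
    list(tis = tis, pr = pr, pro = pro)
  }
  ref0 <- if (!ref_varies)
    simulate_sequence(tissue, NULL, imaging, protocol) else NA_real_
  rows <- purrr::map(values, function(v) {
    s <- at(v)
    s_mt <- simulate_sequence(s$tis, s$pr, imaging, s$pro)
    s_ref <- if (ref_varies)
      simulate_sequence(s$tis, NULL, imaging, s$pro) else ref0
    tibble(value = v, signal_mt = s_mt, signal_ref = s_ref)
  })
  out <- dplyr::bind_rows(rows)
  out$mtr_percent <- compute_mtr(out$signal_mt, out$signal_ref)
  structure(out, class = c("mtr_sweep", class(out)),
            axis = axis, variant = imaging$variant)
}

#' @rdname mtr_sweep
#' @param x An `mtr_sweep`.
#' @param ... Unused.
#' @export
tidy.mtr_sweep <- function(x, ...) {
  out <- as_tibble(x)
  out$axis <- attr(x, "axis")
  out
}

#' @rdname mtr_sweep
#' @export
glance.mtr_sweep <- function(x, ...) {
  tibble(axis = attr(x, "axis"), variant = attr(x, "variant"),
         n = nrow(x), mtr_min = min(x$mtr_percent),
         mtr_max = max(x$mtr_percent),
         mtr_range = max(x$mtr_percent) - min(x$mtr_percent))
}

#' @rdname mtr_sweep
#' @param object An `mtr_sweep`.
#' @export
autoplot.mtr_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$mtr_percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = attr(object, "axis"), y = "MTR (%)",
                  title = paste0("MTR vs ", attr(object, "axis"), " (",
                                 attr(object, "variant"), ")"))
}

#' @importFrom ggplot2 autoplot .data
NULL
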