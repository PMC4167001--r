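#' Read neuron parameter sets from a CSV file
#'
#' The file must contain the columns `C, gL, EL, DeltaT, tauw, b, Vr, VT`
#' (any order; values in pF, nS, mV, mV, ms, pA, mV, mV).  An optional
#' `Vup` column overrides the default detection threshold and an optional
#' `cell` column names the rows.  Unknown extra columns are accepted with a
#' warning.  Rows violating the parameter invariants are rejected with an
#' error naming the row.
#'
#' @param path Path to the CSV file.
#' @return Named list of [neuron_params()], one per row.
#' @export
load_params_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("C", "gL", "EL", "DeltaT", "tauw", "b", "Vr", "VT")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  known <- c(required, "Vup", "cell")
  extra <- setdiff(names(df), known)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  for (col in required)
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' is not numeric")
  out <- vector("list", nrow(df))
  ids <- if ("cell" %in% names(df)) as.character(df$cell)
         else as.character(seq_len(nrow(df)))
  for (i in seq_len(nrow(df))) {
    p <- tryCatch({
      if ("Vup" %in% names(df) && is.finite(df$Vup[i]))
        neuron_params(C = df$C[i], g_L = df$gL[i], E_L = df$EL[i],
                      Delta_T = df$DeltaT[i], V_T = df$VT[i], V_r = df$Vr[i],
                      tau_w = df$tauw[i], b = df$b[i], V_up = df$Vup[i],
                      cell = ids[i])
      else
        neuron_params(C = df$C[i], g_L = df$gL[i], E_L = df$EL[i],
                      Delta_T = df$DeltaT[i], V_T = df$VT[i], V_r = df$Vr[i],
                      tau_w = df$tauw[i], b = df$b[i], cell = ids[i])
    }, error = function(e) stop("row ", i, " (", ids[i], "): ",
                                conditionMessage(e), call. = FALSE))
    out[[i]] <- p
  }
  names(out) <- ids
  out
}

#' Write rate results to CSV
#'
#' Serialises a list of rate results (see [nu_fullfp()], [nu_eif_fw()],
#' [nu0_selfconsistent()]) together with the drive they were computed for
#' into a flat CSV with a fixed column layout.
#'
#' @param results A list; each element is a list with components `cell_id`,
#'   `drive` (a [drive_spec()]) and `rate` (a `rate_result`).
#' @param path Output file path.
#' @param seed Seed recorded in the output (reproducibility bookkeeping).
#' @return The data frame written, invisibly.
#' @export
write_rate_csv <- function(results, path, seed = NA_integer_) {
  cols <- c("cell_id", "method", "mu_Isyn_pA", "sigma_Isyn_pA", "tau_s_ms",
            "nu_Hz", "nu0_Hz", "nu2_Hz", "eps", "converged", "seed")
  rows <- lapply(results, function(r) {
    rr <- r$rate
    data.frame(cell_id = r$cell_id,
               method = rr$method,
               mu_Isyn_pA = r$drive$mu_Isyn,
               sigma_Isyn_pA = r$drive$sigma_Isyn,
               tau_s_ms = r$drive$tau_s,
               nu_Hz = rr$nu_Hz,
               nu0_Hz = if (is.null(rr$nu0_Hz)) NA_real_ else rr$nu0_Hz,
               nu2_Hz = if (is.null(rr$nu2_Hz)) NA_real_ else rr$nu2_Hz,
               eps = if (is.null(rr$eps)) NA_real_ else rr$eps,
               converged = isTRUE(rr$converged),
               seed = seed,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                           cols))
  df <- df[order(df$cell_id, df$method, df$mu_Isyn_pA, df$sigma_Isyn_pA), ,
           drop = FALSE]
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}
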