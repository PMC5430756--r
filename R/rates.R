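#' Absolute substitution rates from per-branch dS/dN and branch ages
#'
#' Scales per-branch synonymous substitution counts (substitutions/site,
#' e.g. CodeML output) to an absolute clade-wide rate: the global dS rate
#' is the sum of branch dS divided by the sum of branch ages in years, and
#' the global dN/dS is the ratio of the summed dN to the summed dS.
#'
#' @param rates data frame with columns `ds`, `dn` (substitutions/site,
#'   non-negative) and `age_years` (branch durations in years, positive).
#' @return list with `ds_per_year` and `dn_ds`.
#' @examples
#' absolute_rate(data.frame(ds = c(0.02, 0.03, 0.05), dn = c(0, 0, 0),
#'                          age_years = c(1e7, 1e7, 2e7)))
#' @export
absolute_rate <- function(rates) {
  stopifnot(is.data.frame(rates),
            all(c("ds", "dn", "age_years") %in% names(rates)),
            nrow(rates) >= 1)
  if (any(rates$ds < 0) || any(rates$dn < 0))
    stop("dS and dN must be non-negative", call. = FALSE)
  if (any(rates$age_years <= 0))
    stop("branch ages must be positive", call. = FALSE)
  s_ds <- sum(rates$ds)
  s_dn <- sum(rates$dn)
  if (s_ds == 0 && s_dn > 0)
    stop("undefined dN/dS: total dS is zero with positive dN", call. = FALSE)
  list(ds_per_year = s_ds / sum(rates$age_years),
       dn_ds = if (s_ds == 0) 0 else s_dn / s_ds)
}

#' Read a per-branch rate table (`branch_id  ds  dn  age_years`)
#'
#' @param path TSV path.
#' @export
read_branch_rates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("branch_id", "ds", "dn", "age_years") %in% names(df)))
  df
}
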