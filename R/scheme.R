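#' The default economy-society-healthcare indicator scheme
#'
#' Returns the 20-indicator evaluation scheme used throughout the package:
#' indicators `x1`--`x20` grouped into eight subsystems (`Z1`--`Z8`) and
#' three systems (economy, society, healthcare). The blocks are
#' `Z1 = {x1,x2}` (economic aggregate), `Z2 = {x3,x4}` (economic structure),
#' `Z3 = {x5..x7}` (economic efficiency), `Z4 = {x8,x9}` (public investment),
#' `Z5 = {x10,x11}` (social security), `Z6 = {x12}` (social assistance),
#' `Z7 = {x13..x17}` (healthcare accessibility) and `Z8 = {x18..x20}`
#' (healthcare fairness).
#'
#' All indicators default to `direction = "positive"` (larger is better);
#' the direction can be overridden per indicator before scoring, which
#' routes that indicator through the reversed min-max formula.
#'
#' @return A tibble with columns `id`, `name`, `unit`, `direction`,
#'   `subsystem`, `system`, one row per indicator.
#' @seealso [validate_scheme()], [read_panel()]
#' @export
#' @examples
#' esh_scheme()
esh_scheme <- function() {
  tibble::tribble(
    ~id,   ~name,                                                          ~unit,               ~subsystem,
    "x1",  "GDP",                                                          "100 million yuan",  "Z1",
    "x2",  "Fiscal revenue",                                               "100 million yuan",  "Z1",
    "x3",  "Industrial proportion in GDP",                                 "%",                 "Z2",
    "x4",  "Proportion of tertiary industry in GDP",                       "%",                 "Z2",
    "x5",  "Per-capita GDP",                                               "yuan",              "Z3",
    "x6",  "Per-capita disposable income of urban residents",              "yuan",              "Z3",
    "x7",  "Per-capita disposable income of rural residents",              "yuan",              "Z3",
    "x8",  "General public service expenditure",                           "100 million yuan",  "Z4",
    "x9",  "General public budget expenditure",                            "100 million yuan",  "Z4",
    "x10", "Residents participating in basic endowment insurance",         "10,000 persons",    "Z5",
    "x11", "Persons in the unemployment insurance program",                "10,000 persons",    "Z5",
    "x12", "Urban residents in minimum living security program",           "persons",           "Z6",
    "x13", "Assistant doctors per 1,000 residents",                        "unit",              "Z7",
    "x14", "Registered nurses per 1,000 residents",                        "unit",              "Z7",
    "x15", "Beds per 1,000 residents",                                     "unit",              "Z7",
    "x16", "Households in the basic health care program",                  "10,000 persons",    "Z7",
    "x17", "Birth rate",                                                   "per mille",         "Z7",
    "x18", "Number of tertiary hospitals",                                 "unit",              "Z8",
    "x19", "Number of township hospitals",                                 "unit",              "Z8",
    "x20", "Number of village clinics",                                    "unit",              "Z8"
  ) |>
    dplyr::mutate(
      direction = "positive",
      system = unname(subsystem_system()[.data$subsystem]),
      .after = "unit"
    )
}

# subsystem -> system lookup (named character vector)
subsystem_system <- function() {
  c(Z1 = "economy", Z2 = "economy", Z3 = "economy",
    Z4 = "society", Z5 = "society", Z6 = "society",
    Z7 = "healthcare", Z8 = "healthcare")
}

#' Validate an indicator scheme
#'
#' Checks the structural invariants a scheme must satisfy before scoring:
#' unique indicator ids, directions in `{positive, negative}`, every
#' subsystem mapping to exactly one system, and subsystems partitioning
#' the indicator set.
#'
#' @param scheme a tibble as returned by [esh_scheme()].
#' @return `scheme`, invisibly, if valid; otherwise an error.
#' @export
validate_scheme <- function(scheme) {
  required <- c("id", "name", "unit", "direction", "subsystem", "system")
  missing <- setdiff(required, names(scheme))
  if (length(missing) > 0)
    stop_esh("scheme is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(scheme$id))
    stop_esh("scheme has duplicated indicator ids: ",
             paste(unique(scheme$id[duplicated(scheme$id)]), collapse = ", "))
  bad_dir <- setdiff(unique(scheme$direction), c("positive", "negative"))
  if (length(bad_dir) > 0)
    stop_esh("unknown indicator direction(s): ", paste(bad_dir, collapse = ", "))
  sys_per_sub <- tapply(scheme$system, scheme$subsystem,
                        function(s) length(unique(s)))
  if (any(sys_per_sub > 1))
    stop_esh("subsystem(s) mapped to more than one system: ",
             paste(names(sys_per_sub)[sys_per_sub > 1], collapse = ", "))
  invisible(scheme)
}

# indicator ids belonging to one system, in scheme order
system_indicators <- function(scheme, system) {
  scheme$id[scheme$system == system]
}

# indicator ids belonging to one subsystem, in scheme order
subsystem_indicators <- function(scheme, subsystem) {
  scheme$id[scheme$subsystem == subsystem]
}
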