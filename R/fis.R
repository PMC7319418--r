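# Mamdani fuzzy inference for beaver dam capacity.
#
# Two inference stages: a vegetation stage turning streamside (10 m) and
# riparian (40 m) forage-index values into a vegetation dam capacity, and a
# combined stage turning vegetation capacity, slope and Q80/Q2 stream power
# into the final capacity (dams/km, 0-30). Inference is classical Mamdani:
# trapezoidal memberships, min for AND, rule-output clipping, max
# aggregation and centroid defuzzification on a discretised universe.
#
# The rule lists and membership breakpoints are shipped as editable YAML
# configuration files (inst/extdata/fis_*.yaml) so alternative rule systems
# can be dropped in verbatim.

#' Trapezoidal membership
#' @param x input values.
#' @param p numeric c(a, b, c, d), a <= b <= c <= d; a == b or c == d give
#'   vertical edges (plateaus at universe bounds).
#' @return membership in [0, 1].
#' @export
trapmf <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  left <- if (b > a) (x - a) / (b - a) else as.numeric(x >= a)
  right <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= d)
  pmax(0, pmin(left, right, 1))
}

#' Define a fuzzy variable
#' @param name variable name.
#' @param universe numeric c(lo, hi).
#' @param mfs named list of trapezoid parameter vectors c(a, b, c, d).
#' @return a `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, universe, mfs) {
  stopifnot(length(universe) == 2L, universe[1] < universe[2], length(mfs) >= 1L)
  for (nm in names(mfs)) {
    p <- mfs[[nm]]
    if (length(p) != 4L || is.unsorted(p))
      stop("membership '", nm, "' of '", name, "' must be non-decreasing c(a,b,c,d)")
  }
  # coverage: no point of the universe with all memberships zero
  grid <- seq(universe[1], universe[2], length.out = 513L)
  mu <- vapply(mfs, function(p) trapmf(grid, p), numeric(length(grid)))
  if (any(apply(mu, 1, max) <= 0))
    stop("membership functions of '", name, "' do not cover the universe")
  structure(list(name = name, universe = universe, mfs = mfs),
            class = "fuzzy_variable")
}

#' Assemble and validate a fuzzy inference configuration
#' @param antecedents list of `fuzzy_variable`s.
#' @param consequent a `fuzzy_variable` (the capacity universe).
#' @param rules list of character vectors: one term per antecedent (in
#'   order) followed by the consequent term.
#' @param resolution consequent discretisation step for the centroid.
#' @param and_operator,aggregation,defuzzifier inference operators; only the
#'   classical Mamdani choices ("min", "max", "centroid") are implemented.
#' @return a `fis_config`.
#' @export
fis_config <- function(antecedents, consequent, rules, resolution = 0.01,
                       and_operator = "min", aggregation = "max",
                       defuzzifier = "centroid") {
  stopifnot(and_operator == "min", aggregation == "max",
            defuzzifier == "centroid", resolution > 0)
  na <- length(antecedents)
  for (r in rules) {
    if (length(r) != na + 1L)
      stop("each rule needs ", na, " antecedent terms plus a consequent term")
    for (k in seq_len(na)) {
      if (!r[k] %in% names(antecedents[[k]]$mfs))
        stop("rule references undefined term '", r[k], "' of antecedent '",
             antecedents[[k]]$name, "'")
    }
    if (!r[na + 1L] %in% names(consequent$mfs))
      stop("rule references undefined consequent term '", r[na + 1L], "'")
  }
  structure(list(antecedents = antecedents, consequent = consequent,
                 rules = rules, resolution = resolution,
                 and_operator = and_operator, aggregation = aggregation,
                 defuzzifier = defuzzifier),
            class = "fis_config")
}

#' @export
print.fis_config <- function(x, ...) {
  cat(sprintf("<fis_config: %d antecedents (%s) -> %s, %d rules>\n",
              length(x$antecedents),
              paste(vapply(x$antecedents, `[[`, "", "name"), collapse = ", "),
              x$consequent$name, length(x$rules)))
  invisible(x)
}

#' Evaluate a Mamdani fuzzy inference system
#'
#' Inputs are clipped to the antecedent universes. Per rule the firing
#' strength is the min over antecedent memberships; per consequent term the
#' max firing strength clips that term's trapezoid; the aggregated (max)
#' output set is defuzzified by its centroid over the discretised universe.
#'
#' @param config a `fis_config`.
#' @param inputs matrix or data.frame, one column per antecedent (in config
#'   order), one row per case.
#' @return numeric vector of crisp outputs, within the consequent universe.
#' @export
evaluate_fis <- function(config, inputs) {
  stopifnot(inherits(config, "fis_config"))
  inputs <- as.matrix(inputs)
  na <- length(config$antecedents)
  if (ncol(inputs) != na)
    stop("inputs must have ", na, " columns (one per antecedent)")
  n <- nrow(inputs)
  # clip to universes and evaluate all memberships
  mem <- vector("list", na)
  for (k in seq_len(na)) {
    v <- config$antecedents[[k]]
    x <- pmin(pmax(inputs[, k], v$universe[1]), v$universe[2])
    mem[[k]] <- lapply(v$mfs, trapmf, x = x)
  }
  cons <- config$consequent
  terms <- names(cons$mfs)
  # max firing strength per consequent term
  strength <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  fired <- rep(FALSE, n)
  for (r in config$rules) {
    s <- mem[[1L]][[r[1L]]]
    if (na > 1L) for (k in 2L:na) s <- pmin(s, mem[[k]][[r[k]]])
    ct <- r[na + 1L]
    strength[, ct] <- pmax(strength[, ct], s)
    fired <- fired | s > 0
  }
  if (!all(fired)) {
    i <- which(!fired)[1L]
    stop("input fires zero rules (rule base does not cover this input): (",
         paste(signif(inputs[i, ], 6), collapse = ", "), ")")
  }
  grid <- seq(cons$universe[1], cons$universe[2], by = config$resolution)
  tmf <- vapply(cons$mfs, function(p) trapmf(grid, p), numeric(length(grid)))
  # aggregated membership per grid point and case: max over terms of
  # min(strength, term membership)
  num <- rep(0, n); den <- rep(0, n)
  agg <- matrix(0, length(grid), n)
  for (t in seq_along(terms)) {
    st <- strength[, t]
    hit <- st > 0
    if (!any(hit)) next
    clipped <- pmin(matrix(tmf[, t], length(grid), sum(hit)),
                    matrix(st[hit], length(grid), sum(hit), byrow = TRUE))
    agg[, hit] <- pmax(agg[, hit], clipped)
  }
  num <- as.vector(grid %*% agg)
  den <- colSums(agg)
  out <- num / den
  pmin(pmax(out, cons$universe[1]), cons$universe[2])
}

## -- configuration files --------------------------------------------------

#' Read a fuzzy inference configuration from YAML
#' @param path YAML file (see inst/extdata/fis_vegetation.yaml for the schema).
#' @return a validated `fis_config`.
#' @export
read_fis_config <- function(path) {
  y <- yaml::read_yaml(path)
  mkvar <- function(v) fuzzy_variable(v$name, as.numeric(v$universe),
                                      lapply(v$mfs, as.numeric))
  fis_config(
    antecedents = lapply(y$antecedents, mkvar),
    consequent = mkvar(y$consequent),
    rules = lapply(y$rules, as.character),
    resolution = if (is.null(y$resolution)) 0.01 else y$resolution
  )
}

#' Write a fuzzy inference configuration to YAML
#' @param config a `fis_config`.
#' @param path output file.
#' @export
write_fis_config <- function(config, path) {
  asvar <- function(v) list(name = v$name, universe = v$universe, mfs = v$mfs)
  yaml::write_yaml(list(
    resolution = config$resolution,
    and_operator = config$and_operator,
    aggregation = config$aggregation,
    defuzzifier = config$defuzzifier,
    antecedents = lapply(config$antecedents, asvar),
    consequent = asvar(config$consequent),
    rules = config$rules
  ), path)
  invisible(path)
}

.fis_cache <- new.env(parent = emptyenv())

.load_default_fis <- function(which) {
  if (is.null(.fis_cache[[which]])) {
    path <- system.file("extdata", paste0("fis_", which, ".yaml"),
                        package = "damcap", mustWork = TRUE)
    .fis_cache[[which]] <- read_fis_config(path)
  }
  .fis_cache[[which]]
}

#' Default vegetation-stage FIS configuration
#' @return a `fis_config` with streamside and riparian BFI antecedents.
#' @export
fis_vegetation_config <- function() .load_default_fis("vegetation")

#' Default combined-stage FIS configuration
#' @return a `fis_config` with vegetation capacity, slope and Q80/Q2 stream
#'   power antecedents.
#' @export
fis_combined_config <- function() .load_default_fis("combined")

#' Vegetation dam capacity of reaches
#' @param streamside_bfi,riparian_bfi reach forage values in [0, 5].
#' @param config vegetation FIS configuration.
#' @return capacity supported by vegetation, dams/km.
#' @export
vegetation_capacity <- function(streamside_bfi, riparian_bfi,
                                config = fis_vegetation_config()) {
  if (any(streamside_bfi < 0 | streamside_bfi > 5 |
          riparian_bfi < 0 | riparian_bfi > 5, na.rm = TRUE))
    stop("BFI values must lie in [0, 5]")
  evaluate_fis(config, cbind(streamside_bfi, riparian_bfi))
}

#' Combined dam capacity of reaches
#' @param veg_capacity vegetation-stage capacity (dams/km, 0-30).
#' @param slope dimensionless reach slope (>= 0).
#' @param power_q80,power_q2 stream power (watts) at low and high flow.
#' @param config combined FIS configuration.
#' @return dam capacity, dams/km.
#' @export
combined_capacity <- function(veg_capacity, slope, power_q80, power_q2,
                              config = fis_combined_config()) {
  if (any(veg_capacity < 0 | veg_capacity > 30, na.rm = TRUE))
    stop("veg_capacity must lie in [0, 30]")
  if (any(slope < 0, na.rm = TRUE)) stop("negative slope")
  if (any(power_q80 < 0 | power_q2 < 0, na.rm = TRUE)) stop("negative stream power")
  evaluate_fis(config, cbind(veg_capacity, slope, power_q80, power_q2))
}

## -- constraints and categories -------------------------------------------

#' Constraint thresholds for dam capacity
#' @param max_width_m reaches wider than this have no capacity (default 25).
#' @param max_area_km2 contributing-area cutoff (default 250).
#' @param max_order stream orders above this have no capacity (default 5).
#' @param order5_cap_dpkm cap applied at exactly `max_order` (default 0.9).
#' @return a `constraint_config`.
#' @export
constraint_config <- function(max_width_m = 25, max_area_km2 = 250,
                              max_order = 5, order5_cap_dpkm = 0.9) {
  stopifnot(max_width_m > 0, max_area_km2 > 0, max_order > 0, order5_cap_dpkm > 0)
  structure(list(max_width_m = max_width_m, max_area_km2 = max_area_km2,
                 max_order = max_order, order5_cap_dpkm = order5_cap_dpkm),
            class = "constraint_config")
}

#' Apply physical constraints to dam capacity
#'
#' Wide reaches (lakes/large rivers), large contributing areas and high
#' stream orders cannot hold dams; order-5 reaches are capped.
#' @param capacity dams/km in [0, 30].
#' @param width_m mean bankfull width.
#' @param contrib_area_km2 contributing area.
#' @param order Strahler order.
#' @param cc a `constraint_config`.
#' @return constrained capacity (never larger than the input).
#' @export
apply_constraints <- function(capacity, width_m, contrib_area_km2, order,
                              cc = constraint_config()) {
  out <- capacity
  out[width_m > cc$max_width_m | contrib_area_km2 > cc$max_area_km2 |
        order > cc$max_order] <- 0
  at_cap <- order == cc$max_order
  out[at_cap] <- pmin(out[at_cap], cc$order5_cap_dpkm)
  out
}

#' Dam-capacity category of a reach
#'
#' None {0}; Rare (0, 1]; Occasional (1, 4]; Frequent (4, 15];
#' Pervasive (15, 30]. Half-open intervals make every value in (0, 30]
#' belong to exactly one category.
#' @param capacity dams/km in [0, 30].
#' @return factor with levels None, Rare, Occasional, Frequent, Pervasive.
#' @export
categorize_capacity <- function(capacity) {
  if (any(capacity < 0 | capacity > 30, na.rm = TRUE))
    stop("capacity out of range [0, 30]")
  cut(capacity, breaks = c(-Inf, 0, 1, 4, 15, 30),
      labels = c("None", "Rare", "Occasional", "Frequent", "Pervasive"),
      right = TRUE)
}

#' Expected maximum dams per reach
#' @param capacity dams/km.
#' @param length_m reach length in metres.
#' @return capacity * length in km.
#' @export
max_dams <- function(capacity, length_m) capacity * length_m / 1000
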