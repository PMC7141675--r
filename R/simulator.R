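#' Experimental designs
#'
#' Both designs expose 18 experimental units of 10 organisms each (180
#' organisms total). The categorical design uses 6 concentration levels
#' (0, 6.25, 12.5, 25, 50 and 100 percent effluent) with 3 replicate units
#' per level. The continuous design uses 3 replicate control units plus 15
#' single units at concentrations equally spaced on the natural-log scale
#' from 100 percent down to 2^(-14/3) = 3.94 percent; the spacing ratio is
#' 2^(1/3), so the five non-zero categorical levels reappear exactly.
#'
#' @param name \code{"categorical"} or \code{"continuous"}.
#' @return A \code{design} object: data frame with columns
#'   \code{conc_fraction} and \code{n_exposed}, plus a \code{design_name}
#'   attribute.
#' @examples
#' build_design("categorical")
#' @export
build_design <- function(name = c("categorical", "continuous")) {
  name <- match.arg(name)
  conc <- switch(name,
    categorical = rep(c(0, 0.0625, 0.125, 0.25, 0.5, 1), each = 3L),
    continuous  = c(rep(0, 3L), 2^(-(14:0) / 3))
  )
  d <- data.frame(conc_fraction = conc, n_exposed = 10L)
  attr(d, "design_name") <- name
  class(d) <- c("design", "data.frame")
  d
}

slope_classes <- c(shallow = 3, intermediate = 5, steep = 10)
mortality_classes <- c(low = 0.95, medium = 0.90, high = 0.85)

#' Simulation scenario
#'
#' One cell of the study grid: a curve family (threshold NEC or
#' non-threshold log-logistic), a slope class, a background-mortality class
#' (encoded as the control-survival intercept) and an experimental design.
#' The true threshold of every NEC curve is 20 percent effluent; the
#' matched log-logistic curve shares the NEC curve's intercept and EC50.
#'
#' @param curve_family \code{"nec"} or \code{"loglogistic"}.
#' @param slope_class \code{"shallow"} (m = 3), \code{"intermediate"}
#'   (m = 5) or \code{"steep"} (m = 10).
#' @param mortality_class \code{"low"} (intercept 0.95), \code{"medium"}
#'   (0.90) or \code{"high"} (0.85).
#' @param design_name \code{"categorical"} or \code{"continuous"}.
#' @param n_datasets Number of datasets the study generates for this
#'   scenario (study default 1000).
#' @return A \code{scenario} object carrying the design, the generating
#'   parameters (\code{$truth}) and the scenario id string.
#' @export
scenario <- function(curve_family = c("nec", "loglogistic"),
                     slope_class = c("shallow", "intermediate", "steep"),
                     mortality_class = c("low", "medium", "high"),
                     design_name = c("categorical", "continuous"),
                     n_datasets = 1000L) {
  curve_family <- match.arg(curve_family)
  slope_class <- match.arg(slope_class)
  mortality_class <- match.arg(mortality_class)
  design_name <- match.arg(design_name)
  nec <- nec_params(intercept = mortality_classes[[mortality_class]],
                    slope = slope_classes[[slope_class]],
                    threshold = 0.20)
  truth <- if (curve_family == "nec") nec else matched_loglogistic(nec)
  structure(list(
    curve_family = curve_family,
    slope_class = slope_class,
    mortality_class = mortality_class,
    design_name = design_name,
    design = build_design(design_name),
    truth = truth,
    n_datasets = as.integer(n_datasets),
    id = paste(curve_family, slope_class, mortality_class, design_name,
               sep = "_")
  ), class = "scenario")
}

#' Full scenario grid
#'
#' @param n_datasets Datasets per scenario (1000 for the full study).
#' @return List of the 36 \code{scenario} objects (2 families x 3 slopes x
#'   3 mortalities x 2 designs).
#' @export
scenario_grid <- function(n_datasets = 1000L) {
  grid <- expand.grid(
    design_name = c("categorical", "continuous"),
    mortality_class = names(mortality_classes),
    slope_class = names(slope_classes),
    curve_family = c("nec", "loglogistic"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    scenario(grid$curve_family[i], grid$slope_class[i],
             grid$mortality_class[i], grid$design_name[i],
             n_datasets = n_datasets)
  })
}

#' Simulate one survival dataset
#'
#' Draws \code{n_survived ~ Binomial(10, p(x))} for each experimental unit,
#' with p(x) from the scenario's generating curve. Datasets whose mean
#' control survival falls below 80 percent (i.e. below 8 survivors per
#' control unit on average) are discarded and redrawn; the number of
#' rejections is recorded in the result's attributes.
#'
#' @param scn A \code{scenario} object.
#' @param seed Integer seed for this dataset (recorded in provenance).
#' @param max_rejections Safety cap on the rejection loop.
#' @return A \code{survival_dataset}: data frame with columns
#'   \code{unit_id}, \code{conc_fraction}, \code{n_exposed},
#'   \code{n_survived}; attributes \code{scenario_id}, \code{seed},
#'   \code{n_rejected}.
#' @export
simulate_dataset <- function(scn, seed, max_rejections = 1e4L) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(as.integer(seed))
  x <- scn$design$conc_fraction
  n <- scn$design$n_exposed
  p <- survival_prob(scn$truth, x)
  ctrl <- x == 0
  rejections <- 0L
  repeat {
    y <- rbinom(length(x), n, p)
    if (mean(y[ctrl] / n[ctrl]) >= 0.80) break
    rejections <- rejections + 1L
    if (rejections > max_rejections)
      stop("degenerate scenario: control filter rejected more than ",
           max_rejections, " draws", call. = FALSE)
  }
  d <- data.frame(unit_id = seq_along(x), conc_fraction = x,
                  n_exposed = n, n_survived = y)
  attr(d, "scenario_id") <- scn$id
  attr(d, "seed") <- as.integer(seed)
  attr(d, "n_rejected") <- rejections
  class(d) <- c("survival_dataset", "data.frame")
  d
}

#' Coerce a data frame to the dataset schema used by all fitters
#'
#' @param d Data frame with columns \code{conc_fraction}, \code{n_exposed},
#'   \code{n_survived} (extra columns are kept).
#' @return A \code{survival_dataset}.
#' @export
as_survival_dataset <- function(d) {
  req <- c("conc_fraction", "n_exposed", "n_survived")
  if (!all(req %in% names(d)))
    stop("dataset needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(d$n_survived < 0) || any(d$n_survived > d$n_exposed))
    stop("n_survived must lie in [0, n_exposed]", call. = FALSE)
  if (any(d$conc_fraction < 0))
    stop("conc_fraction must be >= 0", call. = FALSE)
  if (is.null(d$unit_id)) d$unit_id <- seq_len(nrow(d))
  class(d) <- c("survival_dataset", "data.frame")
  d
}

#' Write / read datasets in the tidy CSV schema
#'
#' The on-disk schema is one row per experimental unit with columns
#' \code{dataset_id, unit_id, conc_fraction, n_exposed, n_survived}; a JSON
#' sidecar (\code{<path>.json}) records scenario ids, seeds and rejection
#' counts so a simulation is fully reproducible from disk.
#'
#' @param datasets A \code{survival_dataset} or list of them.
#' @param path CSV file path.
#' @return \code{write_datasets_csv} returns \code{path} invisibly;
#'   \code{read_datasets_csv} returns a named list of
#'   \code{survival_dataset} objects.
#' @export
write_datasets_csv <- function(datasets, path) {
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("d%04d", seq_along(datasets))
  rows <- do.call(rbind, lapply(names(datasets), function(id) {
    d <- datasets[[id]]
    cbind(dataset_id = id,
          as.data.frame(d)[c("unit_id", "conc_fraction", "n_exposed",
                             "n_survived")])
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  meta <- lapply(datasets, function(d) list(
    scenario_id = attr(d, "scenario_id"),
    seed = attr(d, "seed"),
    n_rejected = attr(d, "n_rejected")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_datasets_csv
#' @export
read_datasets_csv <- function(path) {
  rows <- read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  out <- lapply(split(rows, rows$dataset_id), function(d) {
    ds <- as_survival_dataset(d[setdiff(names(d), "dataset_id")])
    m <- meta[[d$dataset_id[1]]]
    if (!is.null(m)) {
      attr(ds, "scenario_id") <- m$scenario_id
      attr(ds, "seed") <- m$seed
      attr(ds, "n_rejected") <- m$n_rejected
    }
    ds
  })
  out[unique(rows$dataset_id)]
}

# Deterministic per-dataset child seed below 2^31, derived from the master
# seed plus the scenario identity and dataset index. Keying on the scenario
# id (not its position in a list) makes scenario results independent of
# how the grid is batched.
child_seed <- function(master, scenario_id, dataset_idx) {
  codes <- utf8ToInt(scenario_id)
  h <- sum(codes * seq_along(codes)) %% 100003
  s <- (as.double(master) %% 1e6) * 1009 + h * 131071 + dataset_idx * 7919
  as.integer(s %% 2147483562 + 1)
}
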