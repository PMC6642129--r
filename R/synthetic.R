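#' Genotype archetypes for synthetic hypocotyl data
#'
#' Linear response presets (hypocotyl length in mm against relative R:IR
#' ratio r, with r at 22 degC = 1) for the Arabidopsis genotypes whose
#' thermomorphogenic responses characterize the model: wild-type controls
#' with strong negative slopes, the phytochrome-null *phyABCDE* and
#' chromophore-deficient *hy1* mutants with reduced sensitivity, and the
#' constitutively active *YHB* line that is nearly insensitive to the R:IR
#' ratio. The three wild-type-like presets come from independent experiments
#' and are kept separate: `control` (grown alongside *phyABCDE*), `Col-0_3d`
#' (alongside the *phyB*/*YHB* transgenics) and `Col-0_3e` (alongside *hy1*).
#'
#' @param noise_sd Replicate noise standard deviation attached to every
#'   archetype, mm.
#' @return A named list of `genotype_archetype` objects, each with fields
#'   `name`, `slope` (mm per unit r), `intercept` (mm) and `noise_sd` (mm).
#' @examples
#' builtin_archetypes()[["phyABCDE"]]
#' @export
builtin_archetypes <- function(noise_sd = 0.5) {
  presets <- list(
    control    = c(-16.177,  20.27),
    phyABCDE   = c(-7.2727,  19.762),
    `phyB-GFP` = c(-14.489,  18.397),
    `Col-0_3d` = c(-14.879,  18.705),
    YHB        = c(-1.5748,  2.9523),
    `Col-0_3e` = c(-14.853,  18.662),
    hy1        = c(-8.2234,  18.489)
  )
  lapply(stats::setNames(names(presets), names(presets)), function(nm) {
    genotype_archetype(nm, presets[[nm]][1L], presets[[nm]][2L], noise_sd)
  })
}

#' @rdname builtin_archetypes
#' @param name Genotype label.
#' @param slope Generative slope, mm per unit relative R:IR ratio.
#' @param intercept Generative intercept, mm.
#' @export
genotype_archetype <- function(name, slope, intercept, noise_sd = 0.5) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(slope), is.numeric(intercept),
            is.numeric(noise_sd), noise_sd >= 0)
  structure(list(name = name, slope = slope, intercept = intercept,
                 noise_sd = noise_sd),
            class = "genotype_archetype")
}

#' Generate a synthetic hypocotyl-length dataset
#'
#' Emulates per-seedling hypocotyl measurements across growth temperatures.
#' For each temperature T the relative R:IR ratio r = r(22 degC, T) is
#' computed from the radiometry model, and `n_per_temp` seedling lengths are
#' drawn from Normal(intercept + slope * r, noise_sd^2), truncated below at
#' 0.1 mm so lengths stay physical. The draw is fully determined by `seed`
#' (Mersenne-Twister, set locally; the caller's RNG state is restored).
#'
#' @param archetype A `genotype_archetype` (see [builtin_archetypes()]).
#' @param temperatures_c Growth temperatures, degC.
#' @param n_per_temp Seedlings per temperature (default 15, the conventional
#'   replication for hypocotyl assays).
#' @param seed Integer seed recorded in the dataset.
#' @inheritParams spectral_energy_density
#' @return A data frame of class `hypocotyl_dataset` with columns `genotype`,
#'   `temperature_C`, `relative_r`, `replicate_index`, `length_mm`, `seed`.
#' @examples
#' ds <- generate_hypocotyl_data(builtin_archetypes()[["Col-0_3e"]], seed = 42)
#' head(ds)
#' @export
generate_hypocotyl_data <- function(archetype,
                                    temperatures_c = default_temperatures_c(),
                                    n_per_temp = 15L,
                                    seed = 1L,
                                    constants = physical_constants()) {
  stopifnot(inherits(archetype, "genotype_archetype"),
            n_per_temp >= 1L, length(temperatures_c) >= 1L)
  t_k <- celsius_to_kelvin(temperatures_c)  # validates temperatures
  r <- relative_r_ir_ratio(celsius_to_kelvin(reference_temperature_c()), t_k,
                           constants)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  rows <- lapply(seq_along(temperatures_c), function(i) {
    mu <- archetype$intercept + archetype$slope * r[i]
    len <- stats::rnorm(n_per_temp, mean = mu, sd = archetype$noise_sd)
    data.frame(
      genotype = archetype$name,
      temperature_C = temperatures_c[i],
      relative_r = r[i],
      replicate_index = seq_len(n_per_temp),
      length_mm = pmax(len, 0.1),
      seed = as.integer(seed)
    )
  })
  structure(do.call(rbind, rows),
            class = c("hypocotyl_dataset", "data.frame"))
}

#' Hypocotyl dataset CSV round-trip
#'
#' Writes and reads the six dataset columns (`genotype, temperature_C,
#' relative_r, replicate_index, length_mm, seed`). Numeric columns use full
#' precision (17 significant digits), so write/read round-trips losslessly
#' and repeated writes of the same dataset are byte-identical.
#'
#' @param dataset A `hypocotyl_dataset`.
#' @param path CSV path.
#' @return `write_hypocotyl_csv()`: `path`, invisibly.
#'   `read_hypocotyl_csv()`: a `hypocotyl_dataset`.
#' @export
write_hypocotyl_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "hypocotyl_dataset"))
  d <- as.data.frame(dataset)
  for (col in c("relative_r", "length_mm")) {
    d[[col]] <- sprintf("%.17g", d[[col]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypocotyl_csv
#' @export
read_hypocotyl_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(
                         genotype = "character", temperature_C = "numeric",
                         relative_r = "numeric", replicate_index = "integer",
                         length_mm = "numeric", seed = "integer"
                       ))
  structure(d, class = c("hypocotyl_dataset", "data.frame"))
}
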