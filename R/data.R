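# Tabulated experimental properties at 25 degC and 1 atm for eight common
# liquids: effective hard-sphere diameter sigma (A), molar volume v1
# (cm^3/mol), isobaric expansion coefficient alpha_P (K^-1), and the
# literature value of the repulsive volume b1 (A^3) under the 0.64
# random-close-packing convention.
.solvent_table <- tibble::tribble(
  ~name,       ~sigma, ~v1,    ~alpha_P,  ~b1_ref,
  "water",      2.80,   18.07,  0.257e-3,  18.0,
  "methanol",   3.83,   40.73,  1.189e-3,  46.0,
  "ethanol",    4.44,   58.68,  1.089e-3,  71.6,
  "CCl4",       5.37,   97.09,  1.226e-3, 126.7,
  "n-hexane",   5.92,  131.62,  1.390e-3, 169.7,
  "n-decane",   7.08,  195.94,  1.020e-3, 290.3,
  "c-hexane",   5.63,  108.75,  1.214e-3, 146.0,
  "benzene",    5.26,   89.40,  1.240e-3, 119.1
)

# Tabulated cavity thermodynamics for a 4 A solute in the same liquids at
# 298.15 K (one-decimal literature precision): the validation reference
# for compare_cavity_reference(). Energies kJ/mol, entropies J/K/mol.
.cavity_reference <- tibble::tribble(
  ~name,       ~dG_c, ~dH_c, ~dS_c, ~dS_x, ~dS_nx,
  "water",      13.0,   2.3, -35.9, -43.6,   7.7,
  "methanol",    8.8,   8.5,  -1.0, -29.5,  28.5,
  "ethanol",     8.3,   8.4,   0.4, -27.8,  28.2,
  "CCl4",        7.6,   9.7,   7.0, -25.5,  32.5,
  "n-hexane",    6.5,   8.8,   7.7, -21.8,  29.5,
  "n-decane",    9.2,  16.5,  24.4, -30.9,  55.3,
  "c-hexane",    7.9,  10.9,  10.1, -26.5,  36.6,
  "benzene",     8.5,  12.0,  11.7, -28.5,  40.2
)

#' Built-in solvent property table
#'
#' Experimental molar volumes and isobaric thermal expansion coefficients
#' at 25 degC and 1 atm, together with effective hard-sphere diameters,
#' for eight common liquids: water, methanol, ethanol, carbon
#' tetrachloride, n-hexane, n-decane, cyclohexane and benzene. `b1_ref`
#' is the tabulated repulsive volume parameter; it agrees with
#' `hard_sphere_b(sigma)` to within 0.1 A^3 and is carried for
#' validation, while computations always derive `b1` from `sigma`.
#'
#' @param compute_b1 If `TRUE` (default) add a `b1` column derived from
#'   `sigma` via [hard_sphere_b()].
#' @return A tibble with columns `name`, `sigma` (A), `v1` (cm^3 mol^-1),
#'   `alpha_P` (K^-1), `b1_ref` (A^3), `reference`, and optionally `b1`.
#' @export
#' @examples
#' builtin_solvents()
builtin_solvents <- function(compute_b1 = TRUE) {
  d <- .solvent_table
  d$reference <- "tabulated-25C-1atm"
  if (compute_b1) d$b1 <- hard_sphere_b(d$sigma)
  d
}

#' Reference cavity thermodynamics for the built-in solvents
#'
#' One-decimal tabulated values of the cavity-creation free energy,
#' enthalpy and entropy components for a 4 A diameter solute in the eight
#' built-in liquids at 298.15 K, used by [compare_cavity_reference()] to
#' validate recomputation.
#'
#' @return A tibble with columns `name`, `dG_c`, `dH_c` (kJ mol^-1),
#'   `dS_c`, `dS_x`, `dS_nx` (J K^-1 mol^-1).
#' @export
cavity_reference <- function() .cavity_reference

#' Read or write a solvent property table
#'
#' Delimited (CSV) tables with header
#' `name,sigma_A,v1_cm3_mol,alpha_P_per_K` and optional `a_attr` and
#' `b1_A3` columns. On read, each row is validated (positive `sigma` and
#' `v1`, numeric cells) with errors naming the offending row, and a
#' missing `b1` is derived from `sigma` via [hard_sphere_b()]. Writing
#' stores full double precision, so a write/read round trip is lossless.
#'
#' @param path File path.
#' @param solvents A solvent tibble as returned by [read_solvent_table()]
#'   or [builtin_solvents()] (columns `name`, `sigma`, `v1`, `alpha_P`,
#'   optional `a_attr`, `b1`).
#' @return `read_solvent_table()` returns a tibble with columns `name`,
#'   `sigma`, `v1`, `alpha_P`, `b1` and, when present in the file,
#'   `a_attr`. `write_solvent_table()` returns `solvents` invisibly.
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_solvent_table(builtin_solvents(), p)
#' read_solvent_table(p)
read_solvent_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Solvent table not found: %s", path),
          class = "vdwsolv_io_error")
  }
  d <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  required <- c("name", "sigma_A", "v1_cm3_mol", "alpha_P_per_K")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    abort(sprintf("Malformed header: missing column(s) %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "vdwsolv_parse_error")
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(x) & !is.na(d[[col]]) | is.na(d[[col]]))
    if (col == "a_attr" || col == "b1_A3") {
      bad <- which(!is.na(d[[col]]) & is.na(x))
    }
    if (length(bad)) {
      abort(sprintf("Non-numeric value in column `%s`, row %d.", col, bad[1]),
            class = "vdwsolv_parse_error")
    }
    x
  }
  out <- tibble(
    name = d$name,
    sigma = num("sigma_A"),
    v1 = num("v1_cm3_mol"),
    alpha_P = num("alpha_P_per_K")
  )
  if ("a_attr" %in% names(d)) out$a_attr <- num("a_attr")
  if (any(out$sigma <= 0)) {
    abort(sprintf("Non-positive sigma in row %d.", which(out$sigma <= 0)[1]),
          class = "vdwsolv_parse_error")
  }
  if (any(out$v1 <= 0)) {
    abort(sprintf("Non-positive molar volume in row %d.",
                  which(out$v1 <= 0)[1]),
          class = "vdwsolv_parse_error")
  }
  out$b1 <- if ("b1_A3" %in% names(d)) {
    b <- num("b1_A3")
    ifelse(is.na(b), hard_sphere_b(out$sigma), b)
  } else hard_sphere_b(out$sigma)
  out
}

#' @rdname read_solvent_table
#' @export
write_solvent_table <- function(solvents, path) {
  d <- validate_solvents(solvents)
  out <- tibble(
    name = d$name, sigma_A = d$sigma, v1_cm3_mol = d$v1,
    alpha_P_per_K = d$alpha_P
  )
  if ("a_attr" %in% names(d)) out$a_attr <- d$a_attr
  out$b1_A3 <- d$b1
  readr::write_csv(out, path, progress = FALSE)
  invisible(solvents)
}

#' Simulate random solvent/solute systems
#'
#' Deterministic (for a fixed seed) generator of synthetic but physically
#' admissible solvent/solute parameter pairs for property testing:
#' diameters uniform on [2, 8] A, solvent molar volume chosen so the
#' packing fraction falls in [0.3, 0.95], expansion coefficients on
#' [0, 2e-3] K^-1 (spanning cold water to volatile organics), attraction
#' parameters on [0, 1e6] kJ cm^3 mol^-2. Every generated system has
#' positive free volume by construction.
#'
#' @param n Number of systems (> 0).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   on exit.
#' @param xi_range,sigma_range,alpha_range,a_range Sampling ranges.
#' @return A tibble with one row per system: solvent columns `name`,
#'   `sigma`, `v1`, `alpha_P`, `b1`, `a_attr`, `xi1` and solute columns
#'   `sigma2`, `b2`, `a2`.
#' @export
#' @examples
#' simulate_solvent_systems(3, seed = 42)
simulate_solvent_systems <- function(n, seed = NULL,
                                     sigma_range = c(2, 8),
                                     xi_range = c(0.3, 0.95),
                                     alpha_range = c(0, 2e-3),
                                     a_range = c(0, 1e6)) {
  stopifnot(n > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  sigma <- stats::runif(n, sigma_range[1], sigma_range[2])
  b1 <- hard_sphere_b(sigma)
  xi1 <- stats::runif(n, xi_range[1], xi_range[2])
  v1 <- .const$N_Av * b1 / (xi1 * 1e24)  # xi1 = rho1 * b1 inverted
  sigma2 <- stats::runif(n, sigma_range[1], sigma_range[2])
  tibble(
    name = sprintf("syn-%03d", seq_len(n)),
    sigma = sigma, v1 = v1,
    alpha_P = stats::runif(n, alpha_range[1], alpha_range[2]),
    b1 = b1, a_attr = stats::runif(n, a_range[1], a_range[2]),
    xi1 = xi1,
    sigma2 = sigma2, b2 = hard_sphere_b(sigma2),
    a2 = stats::runif(n, a_range[1], a_range[2])
  )
}
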