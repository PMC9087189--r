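## Species registry: per-species BSA conversion factor and default body weight.
## Built-ins are the two species of the retrospective analysis (mouse, human);
## anything else is a user extension and may never shadow a built-in.

.species_registry <- new.env(parent = emptyenv())

.builtin_species <- list(
  mouse = list(species_name = "mouse", bsa_factor = 3,  default_body_weight_kg = 0.025),
  human = list(species_name = "human", bsa_factor = 37, default_body_weight_kg = 70)
)

.reset_species_registry <- function() {
  rm(list = ls(.species_registry), envir = .species_registry)
  for (nm in names(.builtin_species)) {
    assign(nm, .builtin_species[[nm]], envir = .species_registry)
  }
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .reset_species_registry()
}

new_species_profile <- function(species_name, bsa_factor, default_body_weight_kg) {
  stopifnot(is.character(species_name), length(species_name) == 1L, nzchar(species_name))
  bsa_factor <- as.numeric(bsa_factor)
  default_body_weight_kg <- as.numeric(default_body_weight_kg)
  if (!is.finite(bsa_factor) || bsa_factor <= 0) {
    stop("species profile '", species_name, "': bsa_factor must be > 0", call. = FALSE)
  }
  if (!is.finite(default_body_weight_kg) || default_body_weight_kg <= 0) {
    stop("species profile '", species_name, "': default_body_weight_kg must be > 0", call. = FALSE)
  }
  structure(
    list(species_name = species_name, bsa_factor = bsa_factor,
         default_body_weight_kg = default_body_weight_kg),
    class = "species_profile"
  )
}

#' Look up a species profile
#'
#' A species profile carries the two constants dose conversion needs: the
#' multiplier from mg/kg to mg/m^2 (the "Km-like" BSA factor) and the default
#' body weight in kg used to normalize absolute mg doses. The built-in
#' registry holds mouse (factor 3, 25 g) and human (factor 37, 70 kg); other
#' species may be added with [register_species()] but built-ins can never be
#' overridden.
#'
#' @param species character scalar species name (case-insensitive), or a
#'   `species_profile` object, which is passed through.
#' @return An object of class `species_profile` with fields `species_name`,
#'   `bsa_factor`, `default_body_weight_kg`.
#' @examples
#' species_profile("mouse")$bsa_factor   # 3
#' species_profile("human")$default_body_weight_kg  # 70
#' @seealso [register_species()], [load_species_profiles()]
#' @export
species_profile <- function(species) {
  if (inherits(species, "species_profile")) {
    return(species)
  }
  stopifnot(is.character(species), length(species) == 1L)
  key <- tolower(trimws(species))
  if (!exists(key, envir = .species_registry, inherits = FALSE)) {
    stop("unknown species '", species, "'; known: ",
         paste(sort(ls(.species_registry)), collapse = ", "), call. = FALSE)
  }
  p <- get(key, envir = .species_registry, inherits = FALSE)
  structure(p, class = "species_profile")
}

#' @rdname species_profile
#' @export
list_species <- function() {
  sort(ls(.species_registry))
}

#' Register a user-supplied species profile
#'
#' Adds a species to the conversion registry. The built-in mouse and human
#' profiles are fixed and an attempt to redefine them is an error; the
#' analysis cites only these two species, so everything else is an explicit
#' user extension.
#'
#' @param species_name species name (registry key; matched case-insensitively).
#' @param bsa_factor multiplier from mg/kg to mg/m^2; must be positive.
#' @param default_body_weight_kg default body weight in kg; must be positive.
#' @param overwrite replace an existing user-supplied profile of the same
#'   name. Built-ins are never replaceable.
#' @return The registered `species_profile`, invisibly.
#' @examples
#' register_species("rat", bsa_factor = 6, default_body_weight_kg = 0.150)
#' mgkg_to_mgm2(2, "rat")  # 12
#' @export
register_species <- function(species_name, bsa_factor, default_body_weight_kg,
                             overwrite = FALSE) {
  key <- tolower(trimws(species_name))
  if (key %in% names(.builtin_species)) {
    stop("cannot override built-in species profile '", key, "'", call. = FALSE)
  }
  if (exists(key, envir = .species_registry, inherits = FALSE) && !overwrite) {
    stop("species '", key, "' already registered; use overwrite = TRUE", call. = FALSE)
  }
  p <- new_species_profile(key, bsa_factor, default_body_weight_kg)
  assign(key, unclass(p), envir = .species_registry)
  invisible(p)
}

#' Load species profiles from a configuration file
#'
#' Reads additional species profiles from a YAML file (a list of entries with
#' keys `species_name`, `bsa_factor`, `default_body_weight_kg`) or a CSV file
#' with those three columns, and registers each via [register_species()].
#' Entries naming the built-in mouse or human profiles are rejected rather
#' than silently overriding them.
#'
#' @param path path to a `.yaml`/`.yml` or `.csv` file.
#' @return Character vector of registered species names, invisibly.
#' @export
load_species_profiles <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    entries <- yaml::read_yaml(path)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("species_name", "bsa_factor", "default_body_weight_kg")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("species config ", path, ": missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    entries <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, need]))
  } else {
    stop("unsupported species config format: .", ext, call. = FALSE)
  }
  nms <- vapply(entries, function(e) {
    register_species(e$species_name, e$bsa_factor, e$default_body_weight_kg,
                     overwrite = TRUE)$species_name
  }, character(1))
  invisible(nms)
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("Species profile: %s\n  mg/kg -> mg/m2 factor: %g\n  default body weight: %g kg\n",
              x$species_name, x$bsa_factor, x$default_body_weight_kg))
  invisible(x)
}
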