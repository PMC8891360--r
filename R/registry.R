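#' Class-code registries
#'
#' A class registry records the semantics of integer land-cover codes: a
#' human-readable name and three flags. `is_constant` marks temporally
#' constant features (water, forest, developed land) that are held to the
#' stricter historical-dominance threshold; `is_crop` marks cultivated
#' classes; `is_developed` marks the developed/road subset used by the road
#' post-processing step. Codes absent from the registry are valid "regular"
#' classes: all three predicates default to `FALSE` for them, so unknown
#' codes degrade gracefully.
#'
#' @param entries data.frame with columns `code` (non-negative integer,
#'   unique), `name` (character), and logical `is_constant`, `is_crop`,
#'   `is_developed`.
#' @param nodata_code integer code reserved for cells with no valid
#'   classification; it never receives a semantic entry and is never a
#'   refinement target.
#' @return An object of class `class_registry`.
#' @seealso [default_registry()], [read_registry()]
#' @export
class_registry <- function(entries, nodata_code = 0L) {
  stopifnot(is.data.frame(entries))
  required <- c("code", "name", "is_constant", "is_crop", "is_developed")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0L) {
    stop("registry entries lack column(s): ", paste(missing, collapse = ", "))
  }
  entries <- entries[required]
  entries$code <- as.integer(entries$code)
  entries$name <- as.character(entries$name)
  for (fl in c("is_constant", "is_crop", "is_developed")) {
    if (!is.logical(entries[[fl]]) || anyNA(entries[[fl]])) {
      stop("registry flag column '", fl, "' must be TRUE/FALSE with no missing values")
    }
  }
  if (anyNA(entries$code) || any(entries$code < 0L)) {
    stop("registry codes must be non-negative integers")
  }
  if (anyDuplicated(entries$code)) {
    dup <- unique(entries$code[duplicated(entries$code)])
    stop("duplicate registry code(s): ", paste(dup, collapse = ", "))
  }
  nodata_code <- as.integer(nodata_code)
  if (nodata_code %in% entries$code) {
    stop("nodata code ", nodata_code, " must not carry a registry entry")
  }
  entries <- entries[order(entries$code), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, nodata_code = nodata_code),
            class = "class_registry")
}

#' Default CDL-style registry
#'
#' The built-in registry for Cropland Data Layer code semantics. Its constant
#' set is exactly the twelve codes treated as temporally constant features:
#' forest (63, 141, 142, 143), developed (82, 121, 122, 123, 124), water
#' (83, 111) and wetlands (87). Corn (1) and soybeans (5) are registered as
#' rotating crop classes. The developed subset {82, 121, 122, 123, 124} is
#' the default set of road-eligible codes for post-processing.
#'
#' @param nodata_code reserved no-classification code (default 0, the CDL
#'   background value).
#' @return A `class_registry`.
#' @examples
#' reg <- default_registry()
#' is_constant_code(reg, c(111, 141, 1))   # TRUE TRUE FALSE
#' @export
default_registry <- function(nodata_code = 0L) {
  entries <- data.frame(
    code = c(1L, 5L, 63L, 82L, 83L, 87L, 111L, 121L, 122L, 123L, 124L,
             141L, 142L, 143L),
    name = c("Corn", "Soybeans", "Forest", "Developed", "Water", "Wetlands",
             "Open Water Perennial", "Developed/Open Space",
             "Developed/Low Intensity", "Developed/Med Intensity",
             "Developed/High Intensity", "Deciduous Forest",
             "Evergreen Forest", "Mixed Forest"),
    is_constant = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE, TRUE, TRUE),
    is_crop = c(TRUE, TRUE, rep(FALSE, 12L)),
    is_developed = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                     TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  class_registry(entries, nodata_code = nodata_code)
}

registry_flag <- function(registry, codes, flag) {
  stopifnot(inherits(registry, "class_registry"))
  idx <- match(as.integer(codes), registry$entries$code)
  out <- registry$entries[[flag]][idx]
  out[is.na(out)] <- FALSE
  out
}

#' Registry predicates
#'
#' Vectorized lookups of code semantics. Total over the integers: codes
#' without an entry (including the nodata code) return `FALSE`.
#'
#' @param registry a `class_registry`.
#' @param codes integer vector of class codes.
#' @return Logical vector the length of `codes`.
#' @export
is_constant_code <- function(registry, codes) {
  registry_flag(registry, codes, "is_constant")
}

#' @rdname is_constant_code
#' @export
is_crop_code <- function(registry, codes) {
  registry_flag(registry, codes, "is_crop")
}

#' @rdname is_constant_code
#' @export
is_developed_code <- function(registry, codes) {
  registry_flag(registry, codes, "is_developed")
}

#' @rdname is_constant_code
#' @export
registry_name <- function(registry, codes) {
  stopifnot(inherits(registry, "class_registry"))
  registry$entries$name[match(as.integer(codes), registry$entries$code)]
}

#' Developed/road codes of a registry
#'
#' @param registry a `class_registry`.
#' @return Integer vector of codes flagged `is_developed`.
#' @export
developed_codes <- function(registry) {
  stopifnot(inherits(registry, "class_registry"))
  registry$entries$code[registry$entries$is_developed]
}

#' Read or write a registry configuration file
#'
#' The registry file is a CSV with header
#' `code,name,is_constant,is_crop,is_developed`; flags are written as
#' `true`/`false`. `read_registry()` starts from a base registry (the
#' built-in default unless overridden) and applies the file's records on top
#' of it, so a file can both override built-in codes and add new ones; an
#' empty file yields the base registry unchanged. Malformed rows are
#' rejected: a flag value other than true/false (case-insensitive, 0/1
#' accepted) or a duplicated code within the file is a format error.
#'
#' @param path file path.
#' @param base registry to extend (default [default_registry()]); pass an
#'   empty-entry registry to read the file standalone.
#' @param registry a `class_registry` to serialize.
#' @return `read_registry()` a `class_registry`; `write_registry()` the path,
#'   invisibly. A write/read round trip reproduces the registry exactly.
#' @export
read_registry <- function(path, base = default_registry()) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) return(base)
  required <- c("code", "name", "is_constant", "is_crop", "is_developed")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("registry file lacks column(s): ", paste(missing, collapse = ", "))
  }
  code <- suppressWarnings(as.integer(raw$code))
  if (anyNA(code)) stop("registry file: non-integer code in 'code' column")
  if (anyDuplicated(code)) {
    stop("registry file: duplicate code(s): ",
         paste(unique(code[duplicated(code)]), collapse = ", "))
  }
  parse_flag <- function(x, col) {
    v <- tolower(trimws(x))
    out <- rep(NA, length(v))
    out[v %in% c("true", "t", "1", "yes")] <- TRUE
    out[v %in% c("false", "f", "0", "no")] <- FALSE
    if (anyNA(out)) {
      bad <- unique(x[is.na(out)])
      stop("registry file: unknown flag value(s) in '", col, "': ",
           paste(bad, collapse = ", "))
    }
    out
  }
  incoming <- data.frame(
    code = code,
    name = raw$name,
    is_constant = parse_flag(raw$is_constant, "is_constant"),
    is_crop = parse_flag(raw$is_crop, "is_crop"),
    is_developed = parse_flag(raw$is_developed, "is_developed"),
    stringsAsFactors = FALSE
  )
  entries <- base$entries[!(base$entries$code %in% incoming$code), , drop = FALSE]
  entries <- rbind(entries, incoming)
  class_registry(entries, nodata_code = base$nodata_code)
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "class_registry"))
  out <- registry$entries
  for (fl in c("is_constant", "is_crop", "is_developed")) {
    out[[fl]] <- ifelse(out[[fl]], "true", "false")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.class_registry <- function(x, ...) {
  cat("<class_registry> ", nrow(x$entries), " codes (",
      sum(x$entries$is_constant), " constant, ",
      sum(x$entries$is_crop), " crop, ",
      sum(x$entries$is_developed), " developed); nodata = ",
      x$nodata_code, "\n", sep = "")
  print(x$entries, ...)
  invisible(x)
}
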