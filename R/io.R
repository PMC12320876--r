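#' Read mortality schedules from a tidy CSV
#'
#' Reads an age-specific mortality-rate file with one row per (location,
#' year, sex, age group).  Required columns: `location`, `year`, `sex`
#' (`female`, `male` or `both`), `age_start`, `age_width` (empty for the
#' open-ended last group) and `mx`.  Rows are grouped into one
#' [mortality_schedule()] per (location, year, sex) cell; each group's
#' grid must start at 0, be contiguous and end with one open interval
#' (violations are reported with their file row numbers).
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return Named list of [mortality_schedule()]s; names are
#'   `"location|year|sex"`.
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("location", "year", "sex", "age_start", "age_width", "mx")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("mortality CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(df$sex), c("female", "male", "both"))
  if (length(bad_sex)) {
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  df$.row <- seq_len(nrow(df)) + 1L          # file line numbers (header = 1)
  key <- paste(df$location, df$year, df$sex, sep = "|")
  out <- lapply(split(df, key), function(gdf) {
    gdf <- gdf[order(gdf$age_start), , drop = FALSE]
    width <- suppressWarnings(as.numeric(gdf$age_width))
    open <- is.na(width) | gdf$age_width %in% ""
    if (sum(open) != 1L || !open[nrow(gdf)]) {
      stop("each (location, year, sex) group needs exactly one open-ended ",
           "age group (empty age_width), the last; offending group: ",
           paste(gdf$location[1L], gdf$year[1L], gdf$sex[1L]),
           call. = FALSE)
    }
    k <- nrow(gdf)
    gap <- which(gdf$age_start[-1L] !=
                   gdf$age_start[-k] + width[-k])
    if (length(gap)) {
      stop("non-contiguous age groups (rows ",
           paste(gdf$.row[gap], gdf$.row[gap + 1L], sep = "-",
                 collapse = ", "),
           " of ", path, "): age ", gdf$age_start[gap[1L]], " has width ",
           width[gap[1L]], " but the next group starts at ",
           gdf$age_start[gap[1L] + 1L], call. = FALSE)
    }
    mortality_schedule(age_grid(gdf$age_start), gdf$mx,
                       location = gdf$location[1L],
                       year = gdf$year[1L], sex = gdf$sex[1L])
  })
  out
}

#' Write mortality schedules to a tidy CSV
#'
#' Inverse of [read_mortality_csv()]; locale-independent (period decimal
#' separator, empty `age_width` marking the open interval).
#'
#' @param schedules A [mortality_schedule()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mortality_csv <- function(schedules, path) {
  if (inherits(schedules, "mortality_schedule")) schedules <- list(schedules)
  rows <- do.call(rbind, lapply(schedules, function(s) {
    data.frame(location = s$label$location, year = s$label$year,
               sex = s$label$sex, age_start = s$grid$starts,
               age_width = ifelse(is.finite(s$grid$widths),
                                  s$grid$widths, NA_real_),
               mx = s$mx, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read cause-of-death tables from a tidy CSV
#'
#' Required columns: `location`, `year`, `sex`, `age_start`, `cause`, and
#' either `fraction` or `deaths` (fractions are derived from deaths within
#' each age group).  Returns one [cause_table()] per (location, year, sex)
#' cell; the grid is inferred from the distinct `age_start` values (last
#' group open-ended).
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return Named list of [cause_table()]s keyed `"location|year|sex"`.
#' @export
read_cause_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("location", "year", "sex", "age_start", "cause")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cause CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  has_frac <- "fraction" %in% names(df)
  if (!has_frac && !"deaths" %in% names(df)) {
    stop("cause CSV needs a `fraction` or `deaths` column", call. = FALSE)
  }
  key <- paste(df$location, df$year, df$sex, sep = "|")
  lapply(split(df, key), function(gdf) {
    starts <- sort(unique(gdf$age_start))
    causes <- unique(gdf$cause)
    g <- age_grid(starts)
    val <- if (has_frac) gdf$fraction else gdf$deaths
    m <- matrix(NA_real_, length(starts), length(causes),
                dimnames = list(NULL, causes))
    m[cbind(match(gdf$age_start, starts), match(gdf$cause, causes))] <- val
    if (anyNA(m)) {
      stop("cause CSV group ", paste(gdf$location[1L], gdf$year[1L],
                                     gdf$sex[1L]),
           " is missing (age, cause) cells", call. = FALSE)
    }
    if (has_frac) cause_table(g, fractions = m, causes = causes)
    else cause_table(g, deaths = m, causes = causes)
  })
}

#' Read population structures from a tidy CSV
#'
#' Required columns: `location`, `year`, `sex`, `age_start`, `age_width`
#' (empty for the open group) and `population`.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return Named list of [population_structure()]s keyed
#'   `"location|year|sex"`.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("location", "year", "sex", "age_start", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("population CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$location, df$year, df$sex, sep = "|")
  lapply(split(df, key), function(gdf) {
    gdf <- gdf[order(gdf$age_start), , drop = FALSE]
    population_structure(age_grid(gdf$age_start), gdf$population)
  })
}

#' Write life-table columns to a tidy CSV
#'
#' One row per (label, age interval) with all derived columns.
#'
#' @param lts A [life_table()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table_csv <- function(lts, path) {
  if (inherits(lts, "life_table")) lts <- list(lts)
  rows <- do.call(rbind, lapply(lts, function(lt) {
    cbind(data.frame(location = lt$label$location, year = lt$label$year,
                     sex = lt$label$sex, stringsAsFactors = FALSE),
          as.data.frame(lt))
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
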