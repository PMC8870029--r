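#' Write a synthetic cohort to disk in the pipeline's file formats
#'
#' Per subject one EDF signal file and one hypnogram TSV, plus one shared
#' covariate CSV and one montage CSV for the cohort. A manifest (tibble and
#' `manifest.json`) lists every written file with its MD5 checksum and size.
#' An empty cohort writes nothing and returns an empty manifest.
#'
#' @param cohort A `sleep_cohort` from [simulate_cohort()].
#' @param directory Output directory (created if missing).
#' @return Tibble with columns `file`, `md5`, `bytes`, invisibly.
#' @export
write_fixtures <- function(cohort, directory) {
  if (length(cohort$subjects) == 0) {
    return(invisible(tibble::tibble(file = character(), md5 = character(),
                                    bytes = numeric())))
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create output directory: ", directory)
    }
  }
  paths <- character()
  wtry <- function(fun, path) {
    tryCatch(fun(path), error = function(e) {
      stop("failed writing ", path, ": ", conditionMessage(e))
    })
    paths <<- c(paths, path)
  }
  for (s in cohort$subjects) {
    wtry(function(p) write_edf(s$recording, p),
         file.path(directory, paste0(s$subject_id, ".edf")))
    wtry(function(p) write_hypnogram(s$hypnogram, p),
         file.path(directory, paste0(s$subject_id, "_hypnogram.tsv")))
  }
  wtry(function(p) utils::write.csv(cohort$subject_table, p,
                                    row.names = FALSE, quote = FALSE),
       file.path(directory, "covariates.csv"))
  wtry(function(p) write_montage(cohort$montage, p),
       file.path(directory, "montage.csv"))

  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    bytes = unname(file.size(paths))
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_fixtures()]
#'
#' @param directory Directory containing the fixture files.
#' @return A `sleep_cohort`-shaped list (recordings, hypnograms, subject
#'   table, montage).
#' @export
read_fixtures <- function(directory) {
  montage <- read_montage(file.path(directory, "montage.csv"))
  st <- tibble::as_tibble(utils::read.csv(file.path(directory,
                                                    "covariates.csv")))
  subjects <- lapply(seq_len(nrow(st)), function(i) {
    id <- st$subject[i]
    list(
      subject_id = id, group = st$group[i],
      recording = read_edf(file.path(directory, paste0(id, ".edf")), montage),
      hypnogram = read_hypnogram(file.path(directory,
                                           paste0(id, "_hypnogram.tsv"))),
      covariates = st[i, ]
    )
  })
  structure(list(subjects = subjects, subject_table = st, montage = montage,
                 roi = NULL),
            class = "sleep_cohort")
}
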