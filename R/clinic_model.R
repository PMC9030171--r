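# The MRI diagnostic pathway: activity catalogue, per-scenario activity graph,
# and per-patient stage chains.
#
# All clock times are seconds since 8:30 a.m. of the running day; the ward
# operates a 12 h window (0 .. 43200 s) and is open to the public for 11 h
# (1800 .. 41400 s).

SEC_DAY <- 43200          # 8:30 a.m. - 8:30 p.m.
PUBLIC_OPEN <- 1800       # 9:00 a.m.
PUBLIC_CLOSE <- 41400     # 8:00 p.m.
FEVER_THRESHOLD_C <- 37.5

ROLE_NAMES <- c("receptionist", "nurse", "physician", "technician",
                "clerk", "cleaner", "mri_machine", "dressing_room")

.pkg_cache <- new.env(parent = emptyenv())

activity_catalogue <- function() {
  if (is.null(.pkg_cache$catalogue)) {
    path <- system.file("extdata", "activities.yaml", package = "clinicdes")
    raw <- yaml::read_yaml(path)$activities
    cat_ <- lapply(raw, function(a) {
      a$duration <- dist_spec(a$family, a$p1, a$p2)
      a$resources <- unlist(a$resources) %||% character()
      a
    })
    names(cat_) <- vapply(cat_, `[[`, "", "name")
    .pkg_cache$catalogue <- cat_
  }
  .pkg_cache$catalogue
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Swap the cached activity catalogue (internal; used in tests to collapse
# duration laws to their means). Returns the previous catalogue.
set_activity_catalogue <- function(cat_) {
  old <- activity_catalogue()
  .pkg_cache$catalogue <- cat_
  invisible(old)
}

#' Build the activity graph for an operating policy
#'
#' Returns the set of activities that exist under a scenario (the ordinary
#' pathway; the pandemic pathway adds entrance screening and cleaning stages;
#' the improved pandemic pathway additionally drops the on-site diagnosis
#' communication and the walk-in booking stream), together with the ordered
#' patient stage skeleton and its two branch points (contrast-medium
#' injection needed or not; single- or multiple-region examination).
#'
#' @param scenario_id One of `"baseline"`, `"covid"`, `"covid_improved"`, or a
#'   [clinic_scenario()] object.
#' @return An object of class `clinic_pathway`: a list with `id`, `activities`
#'   (named list; each element carries a [dist_spec()], resource roles with
#'   their working-state labels, the patient state accrued, and whether the
#'   activity makes the scanner unavailable) and `patient_stages` (ordered
#'   skeleton with branch markers).
#' @export
#' @examples
#' p <- build_pathway("baseline")
#' names(p$activities)
build_pathway <- function(scenario_id) {
  if (inherits(scenario_id, "clinic_scenario")) scenario_id <- scenario_id$scenario_id
  if (!scenario_id %in% c("baseline", "covid", "covid_improved")) {
    stop("unknown scenario_id: ", scenario_id, call. = FALSE)
  }
  cat_ <- activity_catalogue()
  acts <- Filter(function(a) scenario_id %in% a$scenarios, cat_)
  skeleton <- c(
    if (scenario_id != "baseline") c("hand_sanitizing", "temperature_scanning",
                                     "wear_mask_gloves"),
    "registration", "escort_walk", "anamnesis",
    "<if needs_cmi: undress_cmi, cmi | else: undress>",
    "patient_positioning", "<mri_exam_single | mri_exam_multiple>",
    "dress",
    if (scenario_id != "covid_improved") "diagnosis",
    "exit"
  )
  structure(list(id = scenario_id, activities = acts, patient_stages = skeleton),
            class = "clinic_pathway")
}

#' @export
print.clinic_pathway <- function(x, ...) {
  cat(sprintf("<clinic_pathway> %s: %d activities\n", x$id, length(x$activities)))
  cat("  ", paste(names(x$activities), collapse = ", "), "\n")
  invisible(x)
}

# --- internal stage constructors -------------------------------------------

new_stage <- function(act, pstate, res, rstate, dur, mri = 0L, gate = FALSE,
                      parts = NULL, spawn = NULL) {
  list(act = act, pstate = pstate, res = res, rstate = rstate, dur = dur,
       mri = mri, gate = gate, parts = parts, spawn = spawn)
}

stage_from_activity <- function(cat_, name, dur, drop_roles = character()) {
  a <- cat_[[name]]
  res_roles <- setdiff(names(a$resources), drop_roles)
  res <- match(res_roles, ROLE_NAMES)
  mri <- if (a$blocks_mri) {
    if (identical(unname(a$resources[["mri_machine"]]), "blocked")) 2L else 1L
  } else 0L
  new_stage(name, a$patient_state, res, unname(a$resources[res_roles]), dur,
            mri = mri)
}

walk_stage <- function(to, dur, res = integer(), rstate = character()) {
  new_stage(paste0("walk_to_", to), "in_transit", res, rstate, dur)
}

# Sample all durations a patient (or staff task it triggers) will need, and
# assemble the ordered stage chain. Sampling happens in a fixed chain order
# from the patient's private streams - one for the patient's own activities,
# one for the staff consultation, one for cleaning tasks - so the draws are
# independent of how events interleave during the simulation and of whether
# cleaning stages exist in the scenario.
patient_chain <- function(scenario, attrs, streams) {
  cat_ <- activity_catalogue()
  w <- scenario$walk_time_s
  d <- function(name) sample_duration(cat_[[name]]$duration, 1L, stream = streams$dur)
  d_consult <- function() sample_duration(cat_[["check_mri_correctness"]]$duration,
                                          1L, stream = streams$consult)
  d_clean <- function(name) sample_duration(cat_[[name]]$duration, 1L,
                                            stream = streams$clean)

  stages <- list()
  if (scenario$entrance_screening) {
    stages <- c(stages, list(
      stage_from_activity(cat_, "hand_sanitizing", d("hand_sanitizing")),
      stage_from_activity(cat_, "temperature_scanning", d("temperature_scanning"))
    ))
    if (attrs$temperature_c >= FEVER_THRESHOLD_C) {
      return(list(stages = stages, outcome = "rejected"))
    }
    stages <- c(stages, list(
      stage_from_activity(cat_, "wear_mask_gloves", d("wear_mask_gloves"))
    ))
  }

  stages <- c(stages, list(stage_from_activity(cat_, "registration", d("registration"))))

  # Escort from reception to the studio: the nurse walks with the patient
  # unless the improved organisation lets the patient go alone.
  if (attrs$self_escort) {
    stages <- c(stages, list(walk_stage("studio", w)))
  } else {
    stages <- c(stages, list(walk_stage("studio", w, res = match("nurse", ROLE_NAMES),
                                        rstate = "patient_information")))
  }

  drop_anamnesis <- if (scenario$nurse_in_anamnesis) character() else "nurse"
  stages <- c(stages, list(stage_from_activity(cat_, "anamnesis", d("anamnesis"),
                                               drop_roles = drop_anamnesis)))

  if (attrs$needs_cmi) {
    cmi_stage <- stage_from_activity(cat_, "cmi", d("cmi"))
    if (scenario$cleaning_after_exam) {
      cmi_stage$spawn <- list(list(act = "cmi_site_cleaning",
                                   dur = d_clean("cmi_site_cleaning")))
    }
    stages <- c(stages, list(
      walk_stage("triage", w),
      stage_from_activity(cat_, "undress_cmi", d("undress_cmi")),
      cmi_stage,
      walk_stage("mri_room", w)
    ))
  } else {
    stages <- c(stages, list(
      walk_stage("dressing_room", w),
      stage_from_activity(cat_, "undress", d("undress")),
      walk_stage("mri_room", w)
    ))
  }

  # Positioning and the examination hold the technician and the scanner as one
  # uninterrupted block; both durations are known at block start so the
  # end-of-day admission rule can look ahead to the block end.
  exam_act <- if (attrs$exam_type == "single") "mri_exam_single" else "mri_exam_multiple"
  dp <- d("patient_positioning")
  de <- d(exam_act)
  spawn <- list(list(act = "check_mri_correctness", dur = d_consult()))
  if (scenario$cleaning_after_exam) {
    spawn <- c(spawn, list(list(act = "mri_cleaning", dur = d_clean("mri_cleaning"))))
  }
  mri_block <- new_stage("mri_block", "receiving_direct_care",
                         res = match(c("technician", "mri_machine"), ROLE_NAMES),
                         rstate = c("examination", "busy"),
                         dur = dp + de, mri = 1L, gate = TRUE,
                         parts = list(names = c("patient_positioning", exam_act),
                                      durs = c(dp, de)),
                         spawn = spawn)
  stages <- c(stages, list(mri_block))

  dress_stage <- stage_from_activity(cat_, "dress", d("dress"))
  if (scenario$cleaning_after_exam) {
    dress_stage$spawn <- list(list(act = "dressing_room_cleaning",
                                   dur = d_clean("dressing_room_cleaning")))
  }
  stages <- c(stages, list(walk_stage("dressing_room", w), dress_stage))

  if (scenario$onsite_diagnosis) {
    stages <- c(stages, list(
      walk_stage("studio", w),
      stage_from_activity(cat_, "diagnosis", d("diagnosis"))
    ))
  }
  stages <- c(stages, list(walk_stage("exit", w)))
  list(stages = stages, outcome = "completed")
}

# Chain for a booking-only visitor: occupies the receptionist and leaves.
booker_chain <- function(stream) {
  cat_ <- activity_catalogue()
  dur <- sample_duration(cat_[["appointment_booking"]]$duration, 1L, stream = stream)
  list(stages = list(stage_from_activity(cat_, "appointment_booking", dur)),
       outcome = "completed")
}

# Stage for a spawned staff task (consultation or cleaning).
task_stage <- function(act, dur) {
  stage_from_activity(activity_catalogue(), act, dur)
}
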