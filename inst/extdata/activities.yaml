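# Activity catalogue of the MRI diagnostic ward.
# Durations in seconds: normal = (mean, sd), truncated at 0; uniform = (min, max).
# `resources` maps a staffed resource role to the working-state label it accrues.
# `blocks_mri` marks activities during which the scanner cannot serve a patient.
# `scenarios` lists the operating policies in which the activity exists.
activities:
  - name: appointment_booking
    family: normal
    p1: 300
    p2: 13
    patient_state: receiving_indirect_care
    resources: {receptionist: booking_appointments}
    location: reception
    blocks_mri: false
    scenarios: [baseline, covid]
  - name: hand_sanitizing
    family: uniform
    p1: 5
    p2: 10
    patient_state: sanitizing
    resources: {}
    location: entrance
    blocks_mri: false
    scenarios: [covid, covid_improved]
  - name: temperature_scanning
    family: uniform
    p1: 8
    p2: 12
    patient_state: sanitizing
    resources: {clerk: sanitization}
    location: entrance
    blocks_mri: false
    scenarios: [covid, covid_improved]
  - name: wear_mask_gloves
    family: normal
    p1: 300
    p2: 13
    patient_state: sanitizing
    resources: {}
    location: entrance
    blocks_mri: false
    scenarios: [covid, covid_improved]
  - name: registration
    family: normal
    p1: 300
    p2: 13
    patient_state: receiving_indirect_care
    resources: {receptionist: registering_patient}
    location: reception
    blocks_mri: false
    scenarios: [baseline, covid, covid_improved]
  - name: anamnesis
    family: normal
    p1: 300
    p2: 13
    patient_state: receiving_direct_care
    resources: {physician: anamnesis, nurse: anamnesis}
    location: studio
    blocks_mri: false
    scenarios: [baseline, covid, covid_improved]
  - name: undress_cmi
    family: normal
    p1: 180
    p2: 11
    patient_state: receiving_indirect_care
    resources: {}
    location: triage
    blocks_mri: false
    scenarios: [baseline, covid, covid_improved]
  - name: cmi
    family: uniform
    p1: 300
    p2: 600
    patient_state: receiving_direct_care
    resources: {nurse: cmi}
    location: triage
    blocks_mri: false
    scenarios: [baseline, covid, covid_improved]
  - name: undress
    family: normal
    p1: 180
    p2: 11
    patient_state: receiving_indirect_care
    resources: {dressing_room: occupied}
    location: dressing_room
    blocks_mri: false
    scenarios: [baseline, covid, covid_improved]
  - name: patient_positioning
    family: normal
    p1: 120
    p2: 20
    patient_state: receiving_direct_care
    resources: {technician: examination, mri_machine: busy}
    location: mri_room
    blocks_mri: true
    scenarios: [baseline, covid, covid_improved]
  - name: mri_exam_single
    family: uniform
    p1: 900
    p2: 1800
    patient_state: receiving_direct_care
    resources: {technician: examination, mri_machine: busy}
    location: mri_room
    blocks_mri: true
    scenarios: [baseline, covid, covid_improved]
  - name: mri_exam_multiple
    family: uniform
    p1: 2700
    p2: 3600
    patient_state: receiving_direct_care
    resources: {technician: examination, mri_machine: busy}
    location: mri_room
    blocks_mri: true
    scenarios: [baseline, covid, covid_improved]
  - name: dress
    family: normal
    p1: 180
    p2: 11
    patient_state: receiving_indirect_care
    resources: {dressing_room: occupied}
    location: dressing_room
    blocks_mri: false
    scenarios: [baseline, covid, covid_improved]
  - name: check_mri_correctness
    family: normal
    p1: 120
    p2: 20
    patient_state: none
    resources: {technician: staff_consultation, physician: staff_consultation}
    location: mri_room
    blocks_mri: false
    scenarios: [baseline, covid, covid_improved]
  - name: diagnosis
    family: normal
    p1: 300
    p2: 13
    patient_state: receiving_direct_care
    resources: {physician: patient_information, nurse: patient_information}
    location: studio
    blocks_mri: false
    scenarios: [baseline, covid]
  - name: cmi_site_cleaning
    family: normal
    p1: 60
    p2: 2
    patient_state: none
    resources: {cleaner: sanitization}
    location: triage
    blocks_mri: false
    scenarios: [covid, covid_improved]
  - name: mri_cleaning
    family: normal
    p1: 300
    p2: 10
    patient_state: none
    resources: {cleaner: sanitization, mri_machine: blocked}
    location: mri_room
    blocks_mri: true
    scenarios: [covid, covid_improved]
  - name: dressing_room_cleaning
    family: normal
    p1: 120
    p2: 5
    patient_state: none
    resources: {cleaner: sanitization}
    location: dressing_room
    blocks_mri: false
    scenarios: [covid, covid_improved]
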