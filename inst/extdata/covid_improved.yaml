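scenario_id: covid_improved
days: 7
n_day: 20
booking_per_day: 4
p_single: 0.8
p_cmi: 0.3
p_fever: 0.21
p_self_escort: 0.8
walk_time_s: 30.0
dressing_rooms: 2
entrance_screening: yes
cleaning_after_exam: yes
onsite_diagnosis: no
booking_only_stream: no
nurse_in_anamnesis: no
nurse_escort: no
roster:
- role: receptionist
  count: 1
  open_s: 0.0
  close_s: 43200.0
- role: nurse
  count: 1
  open_s: 1800.0
  close_s: 41400.0
- role: physician
  count: 1
  open_s: 1800.0
  close_s: 41400.0
- role: technician
  count: 1
  open_s: 0.0
  close_s: 43200.0
- role: clerk
  count: 1
  open_s: 1800.0
  close_s: 41400.0
- role: cleaner
  count: 1
  open_s: 1800.0
  close_s: 43200.0
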