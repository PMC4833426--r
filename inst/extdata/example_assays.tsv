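assay_id	category	substance_type	screening_stage	on_hold	target_ids	target_type	activity_specified	has_active_outcome
A1	primary	chemical	primary screening	false	T1	protein	false	true
A2	primary	chemical	primary screening	false	T1	protein	false	true
A3	primary	chemical	primary screening	false	T1	protein	false	true
A4	primary	chemical	primary screening	false	T1	protein	false	true
A5	primary	chemical	primary screening	false	T1	protein	false	true
A6	primary	chemical	primary screening	false	T2	protein	false	true
A7	primary	chemical	primary screening	false	T2	protein	false	true
A8	primary	chemical	primary screening	false	T2	protein	false	true
A9	primary	chemical	primary screening	false	T2	protein	false	true
A10	primary	chemical	primary screening	false	T2	protein	false	true
A11	primary	chemical	primary screening	false		cell_based	false	true
A12	primary	RNAi	primary screening	false		other	false	true
C1	confirmatory	chemical	confirmatory, dose-response	false	T1	protein target	true	true
C2	confirmatory	chemical	confirmatory, dose-response	false	T3	protein target	true	true
C3	confirmatory	chemical	confirmatory, dose-response	true	T3	protein target	true	true
C4	confirmatory	chemical	confirmatory, dose-response	false	T1;T3	protein target	true	true
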