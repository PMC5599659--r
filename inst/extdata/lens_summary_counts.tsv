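metric	value
total_transcripts	90689
annotated_transcripts	68166
novel_transcripts	22523
pnt_transcripts	13207
cnt_transcripts	9316
cnt_orf_scanned	654
cnt_with_orf	202
cnt_pfam_hits	121
highconf_broad_orf_scanned	25
highconf_broad_with_orf	13
highconf_broad_pfam_hits	8
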