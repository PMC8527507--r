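# Published genetic-map summary for the Brandes x Wray sweet sorghum RIL
# population: final marker count and total map length after the
# missing-data, informativeness, redundancy, distortion and linkage filters.
stat	value
markers_after_missing_and_informative	11417
markers_after_redundancy	4194
markers_after_distortion	3876
final_map_markers	3767
map_length_cM	1368.83
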