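name	hemisphere	x	y	z	extent	parent
lh_bankssts	lh	-53.9	-46.6	10.3	25	NA
lh_caudalanteriorcingulate	lh	-10	39.6	59.3	25	NA
lh_caudalmiddlefrontal	lh	-45.8	12	54.2	35	NA
lh_cuneus	lh	-6.9	-68.4	21.3	25	NA
lh_entorhinal	lh	-44.6	-17.8	-53.6	20	NA
lh_fusiform	lh	-41.7	-53.6	-23.9	40	NA
lh_inferiorparietal	lh	-35.6	-55.1	29.7	40	NA
lh_inferiortemporal	lh	-54.6	-38.2	-27.2	45	NA
lh_isthmuscingulate	lh	-11.1	-62.2	34.5	20	NA
lh_lateraloccipital	lh	-23.2	-68.1	3.9	40	NA
lh_lateralorbitofrontal	lh	-39.4	55.4	-23.7	35	NA
lh_lingual	lh	-15	-70	-8	35	NA
lh_medialorbitofrontal	lh	-13.3	66.2	-24.9	30	NA
lh_middletemporal	lh	-62.4	-34.1	-11.3	45	NA
lh_parahippocampal	lh	-39.4	-55.4	-23.7	25	NA
lh_paracentral	lh	-8.8	-27.4	66	30	NA
lh_parsopercularis	lh	-65.8	20.6	20.6	25	NA
lh_parsorbitalis	lh	-51.4	48.9	-12.2	20	NA
lh_parstriangularis	lh	-59.6	39.8	6.7	25	NA
lh_pericalcarine	lh	-8.8	-70.9	8.8	25	NA
lh_postcentral	lh	-43.3	-25.7	51.5	45	NA
lh_posteriorcingulate	lh	-9.9	-33.3	63.1	25	NA
lh_precentral	lh	-44.6	-8.9	55.8	45	NA
lh_precuneus	lh	-10.4	-57.6	41.9	40	NA
lh_rostralanteriorcingulate	lh	-11.6	68.4	19.4	25	NA
lh_rostralmiddlefrontal	lh	-41.7	53.6	23.9	45	NA
lh_superiorfrontal	lh	-14.1	29.2	64.3	55	NA
lh_superiorparietal	lh	-22	-48.5	48.5	45	NA
lh_superiortemporal	lh	-69.5	-19	0	45	NA
lh_supramarginal	lh	-51	-40.7	30.5	40	NA
lh_frontalpole	lh	-11.8	71	0	15	NA
lh_temporalpole	lh	-52	22.3	-44.5	20	NA
lh_transversetemporal	lh	-64.5	-28.7	14.3	15	NA
rh_bankssts	rh	53.9	-46.6	10.3	25	NA
rh_caudalanteriorcingulate	rh	10	39.6	59.3	25	NA
rh_caudalmiddlefrontal	rh	45.8	12	54.2	35	NA
rh_cuneus	rh	6.9	-68.4	21.3	25	NA
rh_entorhinal	rh	44.6	-17.8	-53.6	20	NA
rh_fusiform	rh	41.7	-53.6	-23.9	40	NA
rh_inferiorparietal	rh	35.6	-55.1	29.7	40	NA
rh_inferiortemporal	rh	54.6	-38.2	-27.2	45	NA
rh_isthmuscingulate	rh	11.1	-62.2	34.5	20	NA
rh_lateraloccipital	rh	23.2	-68.1	3.9	40	NA
rh_lateralorbitofrontal	rh	39.4	55.4	-23.7	35	NA
rh_lingual	rh	15	-70	-8	35	NA
rh_medialorbitofrontal	rh	13.3	66.2	-24.9	30	NA
rh_middletemporal	rh	62.4	-34.1	-11.3	45	NA
rh_parahippocampal	rh	39.4	-55.4	-23.7	25	NA
rh_paracentral	rh	8.8	-27.4	66	30	NA
rh_parsopercularis	rh	65.8	20.6	20.6	25	NA
rh_parsorbitalis	rh	51.4	48.9	-12.2	20	NA
rh_parstriangularis	rh	59.6	39.8	6.7	25	NA
rh_pericalcarine	rh	8.8	-70.9	8.8	25	NA
rh_postcentral	rh	43.3	-25.7	51.5	45	NA
rh_posteriorcingulate	rh	9.9	-33.3	63.1	25	NA
rh_precentral	rh	44.6	-8.9	55.8	45	NA
rh_precuneus	rh	10.4	-57.6	41.9	40	NA
rh_rostralanteriorcingulate	rh	11.6	68.4	19.4	25	NA
rh_rostralmiddlefrontal	rh	41.7	53.6	23.9	45	NA
rh_superiorfrontal	rh	14.1	29.2	64.3	55	NA
rh_superiorparietal	rh	22	-48.5	48.5	45	NA
rh_superiortemporal	rh	69.5	-19	0	45	NA
rh_supramarginal	rh	51	-40.7	30.5	40	NA
rh_frontalpole	rh	11.8	71	0	15	NA
rh_temporalpole	rh	52	22.3	-44.5	20	NA
rh_transversetemporal	rh	64.5	-28.7	14.3	15	NA
Thalamus	both	0	-13.9	7.7	20	NA
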