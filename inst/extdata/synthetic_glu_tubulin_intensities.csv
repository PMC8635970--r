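"condition","cell","glu_tubulin_intensity"
"low_glucose","low_01",649.1
"low_glucose","low_02",575.7
"low_glucose","low_03",551
"low_glucose","low_04",430.2
"low_glucose","low_05",270.5
"low_glucose","low_06",773.6
"low_glucose","low_07",257.4
"low_glucose","low_08",479.3
"low_glucose","low_09",303.5
"low_glucose","low_10",177.7
"low_glucose","low_11",558.3
"low_glucose","low_12",280.7
"low_glucose","low_13",1114.3
"low_glucose","low_14",529.7
"low_glucose","low_15",406.2
"low_glucose","low_16",614.9
"low_glucose","low_17",648.1
"low_glucose","low_18",282.4
"low_glucose","low_19",683
"low_glucose","low_20",747.6
"low_glucose","low_21",578.8
"low_glucose","low_22",736.6
"low_glucose","low_23",749.1
"low_glucose","low_24",494.8
"low_glucose","low_25",303.5
"low_glucose","low_26",839.1
"low_glucose","low_27",782.2
"low_glucose","low_28",317.9
"low_glucose","low_29",402.2
"low_glucose","low_30",244.7
"low_glucose","low_31",578
"low_glucose","low_32",271.7
"low_glucose","low_33",775.2
"low_glucose","low_34",247.5
"low_glucose","low_35",456.6
"low_glucose","low_36",271.9
"low_glucose","low_37",215.5
"low_glucose","low_38",769.3
"low_glucose","low_39",341.5
"low_glucose","low_40",528
"high_glucose","high_01",84.8
"high_glucose","high_02",299.1
"high_glucose","high_03",411.5
"high_glucose","high_04",645
"high_glucose","high_05",814.1
"high_glucose","high_06",383
"high_glucose","high_07",235
"high_glucose","high_08",240
"high_glucose","high_09",118.7
"high_glucose","high_10",106.7
"high_glucose","high_11",216.4
"high_glucose","high_12",346.2
"high_glucose","high_13",679.1
"high_glucose","high_14",520.6
"high_glucose","high_15",639.3
"high_glucose","high_16",256.3
"high_glucose","high_17",76
"high_glucose","high_18",148.2
"high_glucose","high_19",491.8
"high_glucose","high_20",293.8
"high_glucose","high_21",610.2
"high_glucose","high_22",307.5
"high_glucose","high_23",158.6
"high_glucose","high_24",205.8
"high_glucose","high_25",390.2
"high_glucose","high_26",140.3
"high_glucose","high_27",552.5
"high_glucose","high_28",900.1
"high_glucose","high_29",523.3
"high_glucose","high_30",442.4
"high_glucose","high_31",440
"high_glucose","high_32",94.7
"high_glucose","high_33",1052.4
"high_glucose","high_34",687.4
"high_glucose","high_35",157.1
"high_glucose","high_36",698.5
"high_glucose","high_37",505
"high_glucose","high_38",52.7
"high_glucose","high_39",517.5
"high_glucose","high_40",622
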