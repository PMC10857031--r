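{
  "note": "RECONSTRUCTION: the wearable-sensor column subset yielding 113 channels is not enumerated in the source publication; this file follows the standard wearable-channel selection used by the dataset's deep-learning baselines (body-worn accelerometers and IMUs, quaternion columns excluded). Columns are 1-indexed into the 250-column .dat files; column 1 is the millisecond timestamp.",
  "sensor_columns": [2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31,32,33,34,35,36,37,38,39,40,41,42,43,44,45,46,51,52,53,54,55,56,57,58,59,64,65,66,67,68,69,70,71,72,77,78,79,80,81,82,83,84,85,90,91,92,93,94,95,96,97,98,103,104,105,106,107,108,109,110,111,112,113,114,115,116,117,118,119,120,121,122,123,124,125,126,127,128,129,130,131,132,133,134],
  "label_column": 250,
  "label_codes": [406516, 406517, 404516, 404517, 406520, 404520, 406505, 404505, 406519, 404519, 406511, 404511, 406508, 404508, 408512, 407521, 405506],
  "class_names": ["Open Door 1", "Open Door 2", "Close Door 1", "Close Door 2", "Open Fridge", "Close Fridge", "Open Dishwasher", "Close Dishwasher", "Open Drawer 1", "Close Drawer 1", "Open Drawer 2", "Close Drawer 2", "Open Drawer 3", "Close Drawer 3", "Clean Table", "Drink from Cup", "Toggle Switch"]
}
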