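[{"pore_id":"example-1","eye_id":"eye-A","slice_interval_um":2.6,"slices":[{"z_index":1,"points":[[18.7573239,0],[9.37866194,14.892222],[-9.37866194,14.892222],[-18.7573239,2.10590959e-15],[-9.37866194,-14.892222],[9.37866194,-14.892222]]},{"z_index":2,"points":[[18.8183677,0],[9.40918384,12.865709],[-9.40918384,12.865709],[-18.8183677,1.81934031e-15],[-9.40918384,-12.865709],[9.40918384,-12.865709]]},{"z_index":3,"points":[[18.127008,0],[9.063504,9.68994043],[-9.063504,9.68994043],[-18.127008,1.37025478e-15],[-9.063504,-9.68994043],[9.063504,-9.68994043]]}]},{"pore_id":"example-2","eye_id":"eye-A","slice_interval_um":2.6,"slices":[{"z_index":1,"points":[[72.5048826,25],[66.2524413,34.928148],[53.7475587,34.928148],[47.4951174,25],[53.7475587,15.071852],[66.2524413,15.071852]]},{"z_index":2,"points":[[72.5455785,25],[66.2727892,33.5771393],[53.7272108,33.5771393],[47.4544215,25],[53.7272108,16.4228607],[66.2727892,16.4228607]]},{"z_index":3,"points":[[72.084672,25],[66.042336,31.4599603],[53.957664,31.4599603],[47.915328,25],[53.957664,18.5400397],[66.042336,18.5400397]]}]}]
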