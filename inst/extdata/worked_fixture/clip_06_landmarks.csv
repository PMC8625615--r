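"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,22.91,21.43,24.52,26.68,31.74,38.29,44.07,51.11,54.98,63.87,68.39,75.36,80.8,85.72,89.44,92.06,92.11,25.71,30.4,36.52,43.39,49.59,66.92,71.91,76.57,80.94,85.52,55.94,56.94,56.2,56.46,48.46,53.15,56.05,61,64.16,46.61,41.08,35.68,29.21,31.89,41.58,84.26,79.95,72.95,70.13,74.47,79.09,72.91,70.43,64.89,55.27,48.7,44.09,39.92,44.11,50.14,56.94,63.07,69.81,64.65,65.38,56.27,49.16,46.35,48.99,57.28,62.65,49.64,59.19,65.9,75.26,82.91,84.59,90.62,92.69,95.14,93.64,88.55,83.98,80.2,73.08,66.55,57.3,50.44,30.28,28.87,28.3,28.87,30.62,32.05,30.63,27.68,27.41,29.99,39.9,43.44,49.32,55.35,57,59.31,59.69,59.18,57.23,40.05,37.36,38.27,38.32,42.38,40.68,36.85,37.97,38.57,36.27,41.12,41.78,76.03,73.7,67.56,67.03,68.34,73.51,74.47,79.6,81.47,82.29,81.93,79.64,75.58,73.06,70.67,74.11,75.18,77.72,78.93,77.34
2,25.46,24.38,26.99,28.25,36.41,40.44,44.62,52.06,59.38,65.34,70.67,79.08,81.4,88.58,92.03,93.72,93.64,28.65,33.66,39.92,42.71,49.48,67.85,73.4,78.61,84.26,86.5,57.07,60.45,58.96,58.95,49.93,57.52,59.47,62.48,68.36,47.12,40.78,34.99,33.47,34.84,44.97,86.17,81.86,75.29,73.21,76.27,82.09,75.35,70.88,66.72,59.43,51.29,45.14,42.17,44.42,52.31,58,64.4,71.28,69.42,65.42,58.94,50.97,48.21,51.21,59.14,65.42,49.48,60.34,65.52,73.52,80.26,85.29,91.75,91.86,91.89,90.61,88.91,86.76,80.24,73.87,65.82,58.08,50.55,29.39,28.97,28.97,28.53,30.16,31.01,27.53,27.18,30.08,29.67,38.28,40.7,49.51,54.73,57.16,59.92,61.78,59.46,56.26,39.09,38.05,36.84,36.35,40.84,39.47,36.15,35.65,36.7,38.81,39.61,40.74,73.22,72.52,69.63,67.66,70.66,72.33,74.87,79.16,80.95,83.62,83.08,78.15,74.95,73.17,70.59,71.36,75.07,77.55,78.94,79.91
3,19.98,21.01,21.62,27.34,32.25,37.17,42.66,47.65,54.2,60.98,66.76,74.02,79.62,85.87,90.52,91.4,91.13,28,32.16,35.89,40.28,46.35,66.7,69.14,75.63,78.74,84.73,56.48,56.22,55.78,54.96,47.86,50.69,53.41,61.13,63.56,45.52,40.7,34.01,30.54,33.93,38.73,82.05,78.99,71.51,69.64,74.7,80.14,70.32,70.91,63.18,57.08,47.68,43.45,38.43,41.31,50.16,56.21,62.65,68.71,68.61,64.67,54.86,47.52,47.48,48.19,58.69,61.33,50.33,58.7,65.49,75.07,81.33,87.18,90.23,92.34,94.85,89.75,89.69,86.73,81.43,72.43,67.29,58.62,50.77,29.65,31.32,28.23,31.2,30.79,31.38,29.9,27.63,29.86,29.93,39.87,44.43,49.2,55.53,58.67,60.61,61.98,60.03,57.39,40.28,35.68,38.33,38.23,41.9,41.12,37.77,36.66,35.45,37.81,44.21,40.72,77.42,74.6,69.7,68.36,68.94,71.26,75.25,78.04,81.67,85.19,83.44,79.76,77.56,74.74,72.41,75.47,76.43,79.06,79.19,77.57
4,20.85,21.48,23.22,23.82,32.84,36.83,41.16,47.83,54.42,61.18,68.06,75.99,79.23,85.88,87.47,91.7,90.7,25.46,30.45,35.38,39.66,46.56,66.71,69.57,74.19,79.84,84.17,54.52,54.67,55.93,53.94,46.29,52.02,58.09,59.96,62.96,43.65,40.18,33.59,27.78,32.88,40.55,82.95,78.88,72.91,67.95,73.74,79.07,70.02,70.51,63.27,54.06,48.33,42.11,38.26,41.37,49.62,55.92,62.15,68.26,65.19,63.68,57.6,48.71,46.34,49.41,55.66,61.43,52.84,59.18,67.94,74.14,82.83,86.49,91.76,92.61,95.14,92.4,91.37,85.87,81.76,73.36,64.44,61.71,52.57,31.56,31.33,29.75,28.93,32.27,31.27,29.92,28,30.76,32.56,39.8,45.37,49.74,55.26,60.03,59.55,60.88,60.82,58.98,40.03,36.51,37.37,39.24,43.52,41.97,39.85,37.36,37.86,38,40.39,41.65,77.49,72.5,70.84,69.45,71.26,71.79,75.77,81.39,82.68,84.75,83.76,79.28,78.87,74.44,72.88,72.83,77.97,79.55,79.73,79.25
5,21.96,20.23,20.93,23.11,30.14,34.29,39.9,47.24,53.77,62.72,67.83,73.07,77.98,83.38,85.99,89.76,89.36,24.72,31.13,34.63,40.53,44.48,64.52,68.46,73.42,78.47,81.82,54.16,54.34,55.74,52.85,46.75,50.09,53.7,58.49,60.78,41.2,38.98,32.73,28.22,31.44,36.69,80.01,77.34,69.92,66.63,69.92,76.14,70.1,68.78,60.35,52.98,43.64,40.02,38.5,41.15,47.04,53.99,59.31,69.07,63.74,61.17,55.93,47.12,45.37,48.65,56.19,58.99,51.79,62.42,67.05,74.27,81.39,86.56,90.75,93.54,92.81,93.24,89.56,87.87,82.71,74.31,67.96,60.77,51.3,32.71,29.96,30.34,30.36,32.43,32.31,29.9,29.86,29.96,30.03,39.91,43,48.56,57,59.51,59.87,61.93,61.94,59.55,39.99,39.96,38.33,38.15,42.5,41.41,38.6,38.2,38.24,40.92,44.28,42.45,75.99,72.21,70.04,70.11,70.96,71.71,77.31,80.75,84.26,88.24,85.28,80.14,77.11,74.5,74.01,75.46,77.8,79.1,80.43,78.85
6,19.92,19.61,21.89,23.82,29.79,33.78,40.47,48.37,55.57,62.08,66.6,73.43,77.12,83.16,86.98,87.71,90.31,24.18,28.95,31.87,39.8,42.78,65.65,69,76.28,79.25,83.59,54.33,54.38,52.95,53.78,46.21,51.99,51.72,57.14,64.45,43.73,38.67,30.38,26.79,31.18,37.49,80.46,77.27,70.33,68.06,71.25,76.25,69.38,67.46,61.45,53.29,46.3,39.05,37.88,39.2,48.68,53.91,61.82,69.98,63.7,61.54,53.46,45.74,44.55,47.1,52.73,61.89,51.96,58.76,68,75.29,83.78,83.53,90.69,92.5,93.63,94.3,90.49,87.41,82.26,75.86,66.56,58.64,52.21,31.71,30.96,29.53,31.29,32.84,33.46,30.24,28.08,29.07,31.33,40.57,43.36,51.18,57.37,59.2,59.35,61.39,59.96,58.84,41.55,39.56,37.02,39.23,42.02,41.88,38.25,38.03,38.03,40.06,42.6,41.84,76.57,74.68,71.63,67.25,70.65,72.82,77.27,83.48,84.79,86.39,84.28,80.08,76.96,73.76,72.72,73.78,77.47,79.13,80.24,80.58
7,20.11,19.01,23.73,24.95,31.02,33.57,41.35,48.68,54.36,61.25,68.85,74.85,77.65,84.46,84.97,90.15,89.84,25.8,26.71,35.74,39.62,45.25,66.04,70.17,75.12,78.95,84.49,54.58,54.57,54.43,52.95,46.12,51.1,53.69,58.82,62.33,42.32,36.93,32.04,26.45,30.19,36.77,82.36,79.32,71.42,66.36,69.26,77.65,70.94,69.14,62.7,54.52,43.96,41.62,40.08,38.97,45.91,53.09,62.42,66.03,66.51,60.91,56.67,45.51,46.23,45.56,56.65,59.7,51.69,60.1,69.45,75.56,83.03,86.23,91.31,91.52,93.28,93.69,90.88,89.45,82.67,77.53,68.03,58.94,51.15,32.84,29.34,30.41,29.07,32.07,29.46,29.34,28.1,28.48,32.87,41.22,44.71,50.85,56.35,58.28,62.19,60.6,61.88,57.46,40.13,37.46,38.37,40.14,41.45,41.76,36.5,38.06,36.27,40.03,41.99,40.87,77.42,73.55,70.43,68.56,71.47,71.56,75.43,81.88,83.79,84.6,84.17,80.66,76.02,75.9,72.31,73.08,77.98,79.01,79.69,79.03
8,18.97,19.21,21.43,24.56,31.03,35.05,40.58,47.12,54.01,62.34,67.29,75.27,79.39,82.57,86.55,89.83,90.36,26.84,29.55,33.62,37.88,43.21,65.05,71.46,74.91,79.43,82.96,55.83,55.27,53.07,53.92,47.48,49.73,54.8,57.4,62.8,42.13,36.86,31.06,28.25,29.9,38.63,80.39,76.47,71.3,68.22,70.51,77.03,69.74,68.48,63.66,53.19,44.54,41.51,38.08,40.17,48.28,54.19,59.89,66.8,63.17,61.52,53.35,47.28,44.56,48.9,52.27,60.37,52.68,61.8,69.61,73.96,83.95,84.99,91.79,94.98,94.66,93.77,89.96,88.13,81.8,75.21,66.98,59.79,52.74,34.08,33.16,30.99,30.08,31.7,31.93,29.14,29.11,30.81,32.46,42.28,46.57,51.13,55.99,58.63,60.66,60.2,60.76,56.8,42.18,39.32,35.61,37.81,42.01,42.05,37.54,38.1,37.33,39.49,43.38,40.76,76.06,74.97,69.83,69.52,70.67,71.69,75.8,81.87,84.28,83.71,85.47,81.52,76.26,74.33,74.87,75.19,75.6,82.67,81.22,80.17
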