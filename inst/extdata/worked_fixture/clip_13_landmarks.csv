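"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,23.36,25.82,26.42,27.82,30.99,38.5,42.93,49.85,57.02,65.24,69.37,74.1,80.39,82.29,87.57,89.97,89.72,28.77,34.56,38.63,45.67,48.22,67.51,69.95,75.03,76.89,85.56,58.44,57.27,59.39,57.2,50.1,51.3,58.26,61.73,65.75,45.32,43.09,34.54,30.7,37.53,40.93,83.3,78.13,70.66,69.71,71.9,78.96,70.57,69.26,63.71,57.54,49.59,44.41,42.71,43.08,50.24,57.01,65.78,70.06,65.06,64.32,54.89,50.14,46.32,49.77,56.41,63.54,52.8,59.02,67.35,74.18,79.55,84.26,88.85,89.58,90.45,90.86,90.83,85.68,82.09,73.67,68.4,61.24,51.5,33.79,32.82,32.57,32.52,32.76,32.61,32.53,31.74,31.8,34.05,41.37,47.11,51.7,56.47,59.59,61.2,60.52,59.73,58.83,41.53,38.67,39.1,41.76,44.22,43.33,41.07,38.67,38.67,40.92,42.73,43.74,72.58,68.15,68.46,64.94,65.77,68.17,71.07,75.69,79.39,79.82,78.73,74.16,72.63,68.45,69,68.52,73.7,74.92,75.5,75.28
2,24.65,27.23,26.7,29.76,34.56,40.6,45.88,52.13,57.57,66.12,69.91,74.76,81.64,85.55,86.93,90.18,90.22,31.97,38.14,40.08,44.57,49.09,69.26,71.86,77.2,79.44,85.82,58.42,58.24,58.86,58.89,49.94,53.13,58.27,62.82,66.61,48.47,43.52,37.23,34.1,38.1,44.12,84,79,73.97,70.58,74.5,79.45,72.49,70.52,65.27,58.32,49.88,44.67,46.31,45.59,51.94,58.98,67.84,70.54,65.47,64.82,58.33,50.08,49.35,53.59,58.04,63.6,49.97,58.77,67.62,76.17,80.78,84.78,89.19,92.34,93.84,90.21,90.4,86.45,80.5,72.92,68.55,61.01,53.37,33.6,31.38,32.23,32.95,33.6,32.93,34.48,31.83,32.03,32.99,42.23,47.32,51.43,56.43,60.8,60.31,62.08,61.58,58.33,40.75,39.95,40.53,42.21,43.08,42.84,41.92,36.58,39.74,41.43,43.71,43.53,73.04,69.78,64.48,64.53,65.92,69.99,73.54,74.47,80.64,82.37,78.97,73.75,70.92,69.8,69.65,71.27,72.48,76.27,75.17,73.7
3,24.29,25.09,26.48,27.48,31,39.13,43.57,51.02,58.28,62.27,69.42,75.83,80.22,85.28,87.67,89.57,89.62,28.86,35.6,39.78,44.26,48.98,65.2,71.19,77.62,79.46,84.29,55.4,56.88,58.44,57.94,51.06,53.33,56.7,60.02,65.28,45.47,42.86,37.32,32.94,35.76,43.4,84.65,78.47,72.22,71.05,73.53,77.58,71.12,69.92,65.83,56.99,49.03,43.55,42.04,44.33,50.14,56.67,65.14,70.1,69.44,63.31,58.32,53.25,47.79,52.15,57.48,65.57,49.94,58.04,67.66,74.84,78.07,85.5,87.64,89.9,91.54,91.27,88.24,83.65,79.4,73.19,65.63,59.34,51.14,33.92,30.13,30.37,30.47,33.47,32.65,30.64,29.78,31.78,31.75,39.73,44.9,50.32,54.21,57.87,61.05,60.92,61.09,60.38,39.61,38.05,41.23,38.12,45.25,41.31,39.29,35.85,37.53,40.47,42.98,39.85,72.75,68.02,66.84,65.78,66.2,67.96,75.24,77.53,82.03,80.87,78.83,72.92,73.73,67.6,68.47,68.49,71.53,74.63,75.87,75.85
4,23.16,21.52,24.97,26.94,30.36,38.65,41.54,49.19,56.14,62.59,67.58,73.1,77.35,83.18,83.91,86.62,89.11,29.34,31.18,36.89,40.26,45.39,64.38,70.27,74.4,77.54,83.86,54.01,54.76,55.95,55.02,45.58,49,53.29,57.59,61.21,43.44,39.92,33.27,30.21,34.39,39.5,79.07,76.81,69.49,66.94,70.24,75.4,68.54,66.89,62.62,55.29,48.16,42.04,41.1,41.5,48.98,55.94,62.85,67.87,64.86,61.49,55.48,47.89,46.46,50.39,54,61.96,49.79,56.19,69.49,74.32,79.49,84.2,87.45,90.6,91.22,88.08,88.57,83.75,80.54,72.6,63.95,58.65,52.7,33.58,30.01,31.05,30.91,32.51,32.34,31.5,27.93,28.25,31.82,39.3,46.02,50.59,54.49,58.58,58.83,59.98,59.18,59.31,39.55,36.99,36.98,40.31,43.93,40.8,38.37,37.48,38.56,40.04,41.64,41.99,71.3,66.06,63.81,62.25,62.98,65.82,70.85,74.58,77.91,80.59,76.51,72.23,70.35,69.63,67.93,68.06,71.9,74.4,74.82,72.4
5,22.74,24.84,21.42,25.85,32.28,35.54,40.77,48.57,53.1,60.55,65.51,73.22,78.73,84.05,85.27,86.07,88.35,28.16,33.5,34.8,40.79,46.12,63.6,69.24,72.85,76.97,83.45,56.13,56.44,53.28,54.76,47.32,49.82,54.94,60.67,62.81,42.08,37.47,33.78,29.59,33.7,40.16,78.92,76.72,67.16,67.38,71.59,76.33,67.58,64.7,62.73,55.35,46.03,40.75,40.37,42.66,48.31,55.9,62.73,66.84,62.78,60.24,55.34,49.39,45.99,49.1,53.78,59.99,49.65,59.16,66.25,73.96,79.39,84.56,87.85,90.54,89.98,89.62,87.68,85.03,79.24,72.52,64.96,58.9,53.95,30.43,30.36,31.06,31.68,30.49,33.24,32.91,29.7,31.4,32.85,39.23,46.13,49.92,55.13,57.11,61.95,59.57,59.77,57.78,41.15,38.21,38.68,38.61,42.17,41.45,39.81,36.25,38.08,39.63,41.57,44.08,72.45,66.93,62,64.51,64.05,65.33,73.11,72.9,77.23,80.83,77.61,74.39,70.77,67.18,68.68,67.44,70.68,70.98,75.42,72.06
6,20.75,22.13,20.96,26.06,29.89,35.43,40.6,47.92,54.07,59.91,68.44,74.15,76.66,83.06,84.46,87.82,87.33,27.24,32.96,36.9,41.9,45.08,64.19,66.94,73.58,76.68,81.82,54.46,55.07,55.27,55.63,47.06,49.82,52.65,58.67,61.19,44.68,39.13,34.22,28.33,33.1,37.67,81.31,74.31,70.08,65.99,70.03,76.88,67.34,65.64,62.66,54.34,46.89,41.21,40.97,38.86,48.25,55.06,62.53,66.36,64.1,62.43,53.61,46.93,44.42,47.9,53.39,59.58,50.59,60.18,66.34,74.75,80.04,86.6,87.9,91.48,91.02,90.76,90.05,85.08,80.94,72.96,66.66,60.48,53.77,32.84,31.19,31.44,32.36,32.56,32.5,32.39,31.25,29.96,33.11,39.38,44.98,50.31,55.94,57.91,60.27,61.41,61.29,59.55,39.06,39.26,38.11,38.78,40.91,43.31,42.11,38.23,38.69,38.7,41.47,42.53,70.55,67.12,65.53,64.82,63.58,66.55,73.5,75.94,77.27,79.11,77.63,75.39,70.55,67.53,67.59,66.2,72.18,74.46,73.49,73.35
7,25.61,24.43,25.33,27.18,32.9,39.15,42.16,51.27,56.65,63.98,69.33,76.21,80.04,86,87.32,92.04,91.84,29.61,35.67,39.28,43.98,47.73,67.36,68.95,76.5,78.33,85.57,57.05,57.99,57.56,56.89,50.22,52.13,55.8,60.66,63.14,45.47,42.86,36.08,33.76,36.12,40.96,83.26,79.52,72.74,70.66,72.35,78.09,71.5,69.04,65.47,59.34,48.85,43.57,45.7,44.65,50.19,58.38,64.9,68.84,64.57,65.39,56.66,50.67,47.22,52.6,58.28,65.26,50.17,57.69,65.2,72.79,78.52,83.27,88.4,90.98,90.79,89.57,90.66,84.76,80.26,71.3,67.81,58.96,55.86,32.45,29.57,30.48,30.77,31.57,33.54,31.3,29.44,31.4,32.71,39.78,43.74,49.64,54.95,58.98,57.57,60.26,59.26,56.38,40.64,36.93,37.72,37.99,41.97,39.64,39.27,40.12,37.69,39.57,41.87,42.27,72.94,67.47,65.24,63.97,63.8,69.31,71.31,75.88,78.28,79.43,78.88,74.81,71.83,68.96,69.5,69.74,72.61,73.39,74.9,74.8
8,24.98,26.26,25.22,28.87,33.75,40.61,43.75,50.05,58.37,63.68,71.69,75.93,81.15,85.35,87.25,90.12,92.61,30.07,33.74,38.76,42.47,47.61,67.96,70.1,76.76,78.77,86.62,55.52,56.61,59.31,57.74,46.58,51.97,56.67,59.41,65.94,45.12,42.53,36.13,31.6,34.62,41.3,81.11,78.01,71.13,68.1,71.31,77.91,71.93,70.35,64.89,57.6,50.28,43.18,43.24,42.72,52.41,55.48,66.36,69.77,66.04,64.45,56.88,49.2,47.36,51.79,56.56,63.86,51.85,57.04,66.38,75.89,79.56,86.31,87,91.57,92.15,92.39,89.12,85.04,82.11,74.84,65.88,59.72,52.88,33.35,31.54,32.36,32.01,33.47,34.49,32.98,31.66,32.16,33.4,39.66,45.09,50.97,55.14,61.25,60.25,60.77,61.96,59.4,40.82,37.83,39.73,41.16,42.66,41.25,40.69,37.35,37.67,41.07,44.4,43.32,72.83,68.18,66.74,66.05,65.71,70.25,72.62,76.56,80.67,80.08,78.3,76.02,72.96,69.1,70.31,69.47,74.2,74.57,76.02,76.1
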